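test_that("Neo-Hookean stress vanishes in the reference state and is
          compressive under volumetric compression", {
  expect_equal(neo_hookean_stress(diag(3), 0.5, 0.47), matrix(0, 3, 3))
  s <- neo_hookean_stress(diag(c(0.9, 0.9, 0.9)), 0.5, 0.3)
  expect_lt(sum(diag(s)), 0)
  expect_equal(s, t(s))
  expect_error(neo_hookean_stress(diag(c(1, 1, -1)), 0.5, 0.3),
               "degenerate")
})

test_that("Neo-Hookean law converges to isotropic linear elasticity at
          small strain", {
  E <- 0.5; nu <- 0.47; eps <- 1e-3
  # laterally traction-free uniaxial state of the linearised solid
  F <- diag(c(1 - nu * eps, 1 - nu * eps, 1 + eps))
  s <- neo_hookean_stress(F, E, nu)
  expect_equal(s[3, 3], E * eps, tolerance = 0.01)     # ~500 Pa in MPa
  expect_lt(max(abs(c(s[1, 1], s[2, 2]))), 0.02 * E * eps)
  # generic small deformation gradient vs full linear Hooke tensor
  set.seed(42)
  H <- matrix(rnorm(9, sd = 3e-4), 3, 3)
  F2 <- diag(3) + H
  epsT <- (H + t(H)) / 2
  mu <- E / (2 * (1 + nu)); lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  hooke <- lam * sum(diag(epsT)) * diag(3) + 2 * mu * epsT
  expect_equal(neo_hookean_stress(F2, E, nu), hooke,
               tolerance = 0.01)
})

test_that("fibril is tension-only and reaches the nonlinear-spring
          equilibrium under held strain", {
  p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 30,
                       k0 = 2e-15, M = 5)
  st <- fibril_state()
  out <- fibril_stress_update(-0.1, 0.1, st, p)
  expect_identical(out$sigma_f, 0)
  expect_identical(out$state$overstress_q, 0)
  # hold 0.1 strain: overstress decays, stress -> E_f0 e + E_feps e^2/2
  st <- fibril_state()
  sig <- NA
  qs <- numeric(0)
  for (i in 1:2000) {
    out <- fibril_stress_update(0.1, 10, st, p)
    st <- out$state
    sig <- out$sigma_f
    qs <- c(qs, st$overstress_q)
  }
  expect_equal(sig, 2 * 0.1 + 0.5 * 30 * 0.01, tolerance = 1e-6)
  # monotone decay of the overstress after the loading step
  expect_true(all(diff(qs[-1]) <= 1e-12))
})

test_that("Maxwell branch reproduces the standard-linear-solid
          relaxation exponential", {
  E_f0 <- 2; eta <- 947
  p <- material_params(E_nf = 0.3, E_f0 = E_f0, E_feps = 0,
                       k0 = 2e-15, M = 5, eta_fibril = eta)
  tau <- eta / E_f0
  dt <- tau / 100
  eps <- 0.05
  st <- fibril_stress_update(eps, dt, fibril_state(), p)$state
  t_now <- dt
  times <- c(); num <- c()
  while (t_now < 3 * tau) {
    out <- fibril_stress_update(eps, dt, st, p)
    st <- out$state
    t_now <- t_now + dt
    times <- c(times, t_now)
    num <- c(num, out$sigma_f)
  }
  exact <- E_f0 * eps + E_f0 * eps * exp(-times / tau)
  expect_lt(max(abs(num - exact) / exact), 0.01)
})

test_that("dissipation in the Maxwell branch is non-negative for a
          random strain history", {
  p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 50,
                       k0 = 2e-15, M = 5)
  set.seed(7)
  st <- fibril_state()
  for (i in 1:200) {
    e_new <- max(0, 0.05 + cumsum(rnorm(1, 0, 0.01)))
    out <- fibril_stress_update(e_new, 5, st, p)
    # dissipation rate q^2 / eta >= 0 by construction; overstress must
    # always vanish when the fibril leaves tension
    if (e_new <= 0) expect_identical(out$state$overstress_q, 0)
    st <- out$state
  }
  expect_true(TRUE)
})

test_that("permeability follows k0 * J^M", {
  p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
                       k0 = 1e-15, M = 5)
  expect_equal(permeability(1, p), 1e-15)
  p0 <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
                        k0 = 1e-15, M = 0)
  expect_equal(permeability(0.37, p0), 1e-15)
  expect_equal(permeability(0.8, p), 0.32768e-15)
  J <- seq(0.5, 1.5, by = 0.1)
  expect_true(all(diff(permeability(J, p)) > 0))
  expect_error(permeability(-1, p), "degenerate")
})

test_that("fibril network normalisation gives uniaxial tangent E_f0
          along primary directions", {
  for (ratio in c(1, 3, 10)) {
    lay <- fibril_network_layout(primary_weight_ratio = ratio)
    p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 0,
                         k0 = 2e-15, M = 5, eta_fibril = 1e-9)
    # strain just beyond the 1e-4 crimp-recruitment window, still in
    # the linear range of the log-strain measure
    eps <- 1e-3
    states <- replicate(nrow(lay$directions),
                        fibril_state(c(1, 0, 0)), simplify = FALSE)
    # uniaxial strain state along e_r (tiny dashpot: equilibrium stress)
    out <- fibril_network_stress(diag(c(1 + eps, 1, 1)), 1e3, states,
                                 lay, p)
    expect_equal(out$sigma[1, 1] / eps, 2, tolerance = 0.01)
    # and along e_theta (the other primary direction)
    out2 <- fibril_network_stress(diag(c(1, 1, 1 + eps)), 1e3, states,
                                  lay, p)
    expect_equal(out2$sigma[3, 3] / eps, 2, tolerance = 0.01)
  }
})

test_that("network stress stays axisymmetric (no out-of-plane shear)
          under axisymmetric finite deformation", {
  lay <- fibril_network_layout()
  p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
                       k0 = 2e-15, M = 5)
  F <- matrix(c(1.1, 0, 0,  0.05, 0.8, 0,  0, 0, 1.15), 3, 3,
              byrow = TRUE)  # (r, z, theta) frame, F_rz shear
  states <- replicate(nrow(lay$directions), fibril_state(c(1, 0, 0)),
                      simplify = FALSE)
  out <- fibril_network_stress(F, 1, states, lay, p)
  expect_lt(abs(out$sigma[1, 3]), 1e-12)
  expect_lt(abs(out$sigma[2, 3]), 1e-12)
})

test_that("material parameters round-trip through JSON with units
          intact", {
  p <- material_params(E_nf = 0.31, E_f0 = 1.9, E_feps = 104,
                       k0 = 2.4e-15, M = 4.2)
  f <- tempfile(fileext = ".json")
  write_material_params(p, f)
  q <- read_material_params(f)
  expect_equal(unclass(q), unclass(p))
  expect_equal(porosity_from_void_ratio(p$e0), 3.5 / 4.5)
})
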