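test_that("structured mesh has the documented element/node counts and
          boundary tags", {
  m <- build_mesh(creep_geometry(thickness = 1.7))
  expect_equal(nrow(m$elems), 2400)           # 60 x 40 default
  expect_equal(nrow(m$nodes), 61 * 41)
  m1 <- build_mesh(creep_geometry(thickness = 1, n_r = 1, n_z = 1))
  expect_equal(nrow(m1$elems), 1)
  expect_equal(nrow(m1$nodes), 4)
  m2 <- build_mesh(creep_geometry(thickness = 1, n_r = 3, n_z = 2))
  expect_equal(length(m2$axis_nodes), 3)
  expect_equal(length(m2$outer_nodes), 3)
  expect_equal(length(m2$top_nodes), 4)
  expect_equal(length(m2$bottom_nodes), 4)
  # perimeter segments: 2 * (n_r + n_z)
  expect_equal(length(m2$top_nodes) + length(m2$bottom_nodes) +
                 length(m2$axis_nodes) + length(m2$outer_nodes) - 4,
               2 * (3 + 2))
  expect_error(creep_geometry(radius = -1), "radius")
})

test_that("solver matches the analytic linear biphasic creep in the
          no-fibril small-strain limit", {
  p <- material_params(E_nf = 0.5, E_f0 = 1e-12, E_feps = 0,
                       k0 = 2e-15, M = 0, nu = 0.1)
  lb <- linear_biphasic_params(0.5, 0.1, 2e-15, 3.5, 0.01)
  tt <- 10^seq(1, log10(2 * lb$t_gel), length.out = 12)
  sol <- run_creep(p, coarse_geometry(),
                   loading_protocol(0.01, 0.5, 2 * lb$t_gel,
                                    output_times = tt),
                   solver_options(small_strain = TRUE,
                                  bottom_radial_slip = TRUE))
  expect_lt(max(abs(sol$strain / biphasic_unconfined_creep(lb, tt) - 1)),
            0.02)
})

test_that("healthy creep run honours the physical invariants", {
  sol <- healthy_run()
  stp <- attr(sol, "steps")
  # displacement non-decreasing through ramp and hold
  expect_true(all(diff(stp$displacement) > -1e-9))
  # IFLS bounded and non-increasing after the ramp
  ifls <- stp$POR / 0.78
  expect_true(all(ifls >= -1e-6 & ifls <= 1.02))
  post <- stp$time > 0.5
  expect_true(all(diff(ifls[post]) < 1e-3))
  # load balance: platen reaction equals the applied load within 0.5%
  W <- 0.78e6 * pi * 0.0035^2
  expect_lt(max(abs(stp$reaction[post] - W)) / W, 0.005)
  # drained equilibrium: fluid load support below 2%
  expect_lt(sol$IFLS[nrow(sol)], 0.02)
})

test_that("solution is insensitive to mesh refinement, aspect-ratio
          permutation and time-step refinement", {
  p <- healthy_params()
  tt <- 10^seq(log10(0.6), log10(2000), length.out = 15)
  prot <- loading_protocol(0.78, 0.5, 2000, output_times = tt)
  base <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 15,
                                      n_z = 10), prot)
  fine <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 30,
                                      n_z = 20), prot)
  expect_lt(abs(fine$strain[15] / base$strain[15] - 1), 0.005)
  base24 <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 24,
                                        n_z = 16), prot)
  swapped <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 16,
                                         n_z = 24), prot)
  expect_lt(abs(swapped$strain[15] / base24$strain[15] - 1), 0.005)
  fine_dt <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 15,
                                         n_z = 10), prot,
                       solver_options(dt0 = 0.025,
                                      dt_growth = sqrt(1.15),
                                      n_ramp_steps = 16))
  expect_lt(max(abs(fine_dt$displacement - base$displacement)) /
              max(base$displacement), 0.005)
})

test_that("fluid volume change balances the Darcy outflow through the
          permeable edge (small-strain limit)", {
  p <- material_params(E_nf = 0.5, E_f0 = 1e-12, E_feps = 0,
                       k0 = 2e-15, M = 0, nu = 0.1)
  geo <- creep_geometry(thickness = 1.7, n_r = 12, n_z = 8)
  # late consolidation window: the pressure profile spans the whole
  # radius there, so the post-processed boundary gradient is resolved
  tt <- seq(3000, 18000, length.out = 40)
  sol <- run_creep(p, geo, loading_protocol(0.01, 0.5, 18000,
                                            output_times = tt),
                   solver_options(small_strain = TRUE,
                                  store_fields = TRUE))
  fem <- attr(sol, "fem"); mesh <- attr(sol, "mesh")
  fields <- attr(sol, "fields")
  times <- as.numeric(names(fields))
  late <- times >= 3000
  fields <- fields[late]; times <- times[late]
  # tissue volume: Gauss quadrature of the volume ratio with the
  # axisymmetric radial weight
  g <- 0.5773502691896258
  gps <- list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  el <- mesh$elems
  area <- abs((fem$nodes_m[el[, 2], 1] - fem$nodes_m[el[, 1], 1]) *
                (fem$nodes_m[el[, 3], 2] - fem$nodes_m[el[, 2], 2]))
  vol <- vapply(fields, function(x) {
    Jg <- matrix(fe_gauss_J(x, fem), 4, nrow(el))
    tot <- 0
    for (gi in 1:4) {
      gp <- gps[[gi]]
      N <- 0.25 * c((1 - gp[1]) * (1 - gp[2]), (1 + gp[1]) * (1 - gp[2]),
                    (1 + gp[1]) * (1 + gp[2]), (1 - gp[1]) * (1 + gp[2]))
      rg <- as.numeric(matrix(fem$nodes_m[el, 1], nrow(el), 4) %*% N)
      tot <- tot + sum(Jg[gi, ] * rg * area / 4) * 2 * pi
    }
    tot
  }, numeric(1))
  # outflow rate through the outer edge from the nodal pressure gradient
  outflow <- vapply(fields, function(x) {
    pv <- ifelse(fem$dof_p >= 0, x[fem$dof_p + 1L], 0)
    out_n <- mesh$outer_nodes
    nxt <- out_n - (geo$n_z + 1L)        # one column inward
    nxt2 <- out_n - 2L * (geo$n_z + 1L)  # two columns inward
    h <- diff(fem$nodes_m[c(nxt[1], out_n[1]), 1])
    dpdr <- (3 * pv[out_n] - 4 * pv[nxt] + pv[nxt2]) / (2 * h)
    r_edge <- fem$nodes_m[out_n[1], 1]
    z <- fem$nodes_m[out_n, 2]
    wz <- c(diff(z) / 2, 0) + c(0, diff(z) / 2)
    -sum(p$k0 * dpdr * wz) * 2 * pi * r_edge
  }, numeric(1))
  dV <- diff(vol)
  # backward-Euler pairing: the volume change over a step balances the
  # Darcy outflow evaluated at the end of the step
  q_end <- outflow[-1]
  dt <- diff(times)
  expect_lt(abs(sum(dV) + sum(q_end * dt)) / abs(sum(dV)), 0.02)
  # and per step within a few percent (post-processed boundary gradient)
  expect_lt(stats::median(abs(dV + q_end * dt) / abs(dV)), 0.03)
})

test_that("sensitivity sweep reproduces the documented Poisson-ratio
          and permeability behaviour", {
  p <- healthy_params()
  geo <- coarse_geometry()
  tt <- 10^seq(log10(0.6), log10(3000), length.out = 15)
  prot <- loading_protocol(0.78, 0.5, 3000, output_times = tt)
  sw <- sensitivity_sweep(p, geo, prot, "nu", c(0.15, 0.37, 0.47),
                          opts = fit_solver_options())
  expect_length(sw, 3)
  # magnitude/dissipation differ across nu but displacement trend holds
  ifls_mid <- vapply(sw, function(s) s$IFLS[8], numeric(1))
  expect_gt(max(ifls_mid) - min(ifls_mid), 0.005)
  for (s in sw) expect_true(all(diff(s$displacement) > -1e-9))
  # sweeping a value equal to the baseline reproduces the baseline
  base <- run_creep(p, geo, prot, fit_solver_options())
  again <- sensitivity_sweep(p, geo, prot, "nu", 0.47,
                             opts = fit_solver_options())[[1]]
  expect_equal(again$strain, base$strain, tolerance = 1e-12)
  # time to half IFLS decreases as permeability increases
  swk <- sensitivity_sweep(p, geo, prot, "k0",
                           p$k0 * c(0.5, 1, 2),
                           opts = fit_solver_options())
  t_half <- vapply(swk, function(s)
    approx(rev(s$IFLS), rev(s$time), 0.45, ties = "ordered")$y,
    numeric(1))
  expect_true(all(diff(t_half) < 0))
})
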