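#' Parameters of the linear biphasic unconfined-compression problem
#'
#' Describes a linear, isotropic, biphasic (poroelastic) cylinder in
#' frictionless unconfined compression between impermeable platens with a
#' free-draining lateral surface, loaded by a step axial stress. Used as
#' the closed-form verification oracle for the finite-element solver in
#' its no-fibril, small-strain limit.
#'
#' @param E_s Drained Young's modulus \[MPa\].
#' @param nu_s Drained Poisson's ratio, in \[0, 0.5).
#' @param k Permeability \[m^4/(N s)\].
#' @param radius Cylinder radius \[mm\].
#' @param sigma0 Applied compressive stress \[MPa\] (positive).
#' @return A `linear_biphasic_params` list; includes derived Lame
#'   constants, aggregate modulus `H_A` \[MPa\] and the gel diffusion
#'   time `t_gel = a^2 / (H_A k)` \[s\].
#' @export
linear_biphasic_params <- function(E_s, nu_s, k, radius, sigma0) {
  stopifnot(E_s > 0, nu_s >= 0, nu_s < 0.5, k > 0, radius > 0, sigma0 > 0)
  mu <- E_s / (2 * (1 + nu_s))
  lambda <- E_s * nu_s / ((1 + nu_s) * (1 - 2 * nu_s))
  H_A <- lambda + 2 * mu
  a_m <- radius * 1e-3
  t_gel <- a_m^2 / (H_A * 1e6 * k)
  structure(list(E_s = E_s, nu_s = nu_s, k = k, radius = radius,
                 sigma0 = sigma0, mu = mu, lambda = lambda, H_A = H_A,
                 t_gel = t_gel),
            class = "linear_biphasic_params")
}

# Characteristic function whose positive roots beta_n give the creep
# eigenvalues s_n = -beta_n^2 / t_gel. Derived from the Laplace-domain
# solution: eps_hat(s) = (sigma0/s) * N(x)/D(x) with x = a sqrt(s/(H_A k)),
# N = H_A I0(x) - 2 mu I1(x)/x, D = mu (3 H_A I0(x) - 8 mu I1(x)/x);
# on the negative real s axis (x = i beta) D becomes the expression below.
biphasic_char_fn <- function(beta, H_A, mu) {
  3 * H_A * besselJ(beta, 0) - 8 * mu * besselJ(beta, 1) / beta
}

# First n positive roots of the characteristic equation, by sign-change
# scan plus bracketed bisection (uniroot).
biphasic_char_roots <- function(H_A, mu, n_roots) {
  grid <- seq(1e-4, (n_roots + 3) * pi, by = 0.02)
  vals <- biphasic_char_fn(grid, H_A, mu)
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- stats::uniroot(biphasic_char_fn, c(grid[i], grid[i + 1]),
                        H_A = H_A, mu = mu, tol = 1e-12)$root
    roots <- c(roots, r)
    if (length(roots) >= n_roots) break
  }
  if (length(roots) < n_roots)
    stop("failed to bracket the requested number of characteristic roots")
  roots
}

#' Closed-form linear biphasic unconfined-compression creep strain
#'
#' Bessel-series solution for the axial strain of a biphasic cylinder
#' under a step compressive stress, obtained by residue inversion of the
#' exact Laplace-domain response. Instantaneous response is the
#' incompressible elastic limit `sigma0 / (3 mu)`; the equilibrium is the
#' drained uniaxial value `sigma0 / E_s`.
#'
#' @param params A [linear_biphasic_params()].
#' @param t Time vector \[s\], non-negative.
#' @param n_roots Number of series terms (characteristic roots);
#'   increased automatically until the successive-term ratio at the
#'   earliest positive requested time is below `1e-8`.
#' @return Axial (compressive, positive) strain at `t`.
#' @export
#' @examples
#' p <- linear_biphasic_params(E_s = 0.5, nu_s = 0.1, k = 2e-15,
#'                             radius = 3.5, sigma0 = 0.01)
#' eps <- biphasic_unconfined_creep(p, c(10, 100, 1000))
biphasic_unconfined_creep <- function(params, t, n_roots = 50) {
  stopifnot(inherits(params, "linear_biphasic_params"), all(t >= 0))
  H_A <- params$H_A; mu <- params$mu
  t_gel <- params$t_gel
  t_chk <- if (any(t > 0)) min(t[t > 0]) else 0
  repeat {
    beta <- biphasic_char_roots(H_A, mu, n_roots)
    s_n <- -beta^2 / t_gel
    # residue of sigma0 N e^{st} / (s D) at each root of D
    Nb <- H_A * besselJ(beta, 0) - 2 * mu * besselJ(beta, 1) / beta
    dD_dbeta <- mu * (-3 * H_A * besselJ(beta, 1) -
                        8 * mu * (besselJ(beta, 0) / beta -
                                    2 * besselJ(beta, 1) / beta^2))
    dbeta_ds <- -t_gel / (2 * beta)
    dD_ds <- dD_dbeta * dbeta_ds
    coef <- params$sigma0 * Nb / (s_n * dD_ds)
    if (t_chk > 0) {
      terms <- abs(coef * exp(s_n * t_chk))
      n_terms <- length(terms)
      ratio <- terms[n_terms] / max(terms[1], .Machine$double.xmin)
      if (ratio > 1e-8 && n_roots < 2000) {
        n_roots <- n_roots * 2
        next
      }
    }
    break
  }
  eq <- params$sigma0 / params$E_s
  sapply(t, function(ti) {
    if (ti == 0) return(params$sigma0 / (3 * mu))
    eq + sum(coef * exp(s_n * ti))
  })
}

#' Brute-force finite-difference biphasic unconfined creep
#'
#' Independent 1D radial backward-Euler consolidation solver for the same
#' problem as [biphasic_unconfined_creep()]: unknowns are the radial
#' displacement profile, pore pressure profile, and the (uniform) axial
#' strain, coupled through radial equilibrium, Darcy continuity, the
#' free-draining lateral boundary, and the axial force constraint. Used
#' in tests to verify the Bessel series; shares no code with it or with
#' the finite-element solver.
#'
#' @param params A [linear_biphasic_params()].
#' @param t Output times \[s\], positive, increasing.
#' @param n_r Number of radial nodes.
#' @param dt0 Initial time step \[s\] (grows geometrically by 5 percent).
#' @return Axial strain at `t`.
#' @export
biphasic_creep_fd <- function(params, t, n_r = 201, dt0 = NULL) {
  stopifnot(inherits(params, "linear_biphasic_params"),
            all(diff(t) > 0), all(t > 0))
  # nondimensional formulation: lengths / a, stresses / H_A, times / t_gel
  t <- t / params$t_gel
  H_A <- 1
  lambda <- params$lambda / params$H_A
  k <- 1
  a <- 1
  sigma0 <- params$sigma0 / params$H_A
  N <- n_r
  h <- a / (N - 1)
  r <- seq(0, a, length.out = N)
  iu <- seq_len(N); ip <- N + seq_len(N); iez <- 2 * N + 1
  if (is.null(dt0)) dt0 <- 1e-5 else dt0 <- dt0 / params$t_gel

  build_system <- function(dt) {
    A <- matrix(0, 2 * N + 1, 2 * N + 1)
    # axis: u(0) = 0
    A[iu[1], iu[1]] <- 1
    # interior radial equilibrium: H_A (u'' + u'/r - u/r^2) - p' = 0
    for (i in 2:(N - 1)) {
      ri <- r[i]
      A[iu[i], iu[i - 1]] <- H_A * (1 / h^2 - 1 / (2 * h * ri))
      A[iu[i], iu[i]]     <- H_A * (-2 / h^2 - 1 / ri^2)
      A[iu[i], iu[i + 1]] <- H_A * (1 / h^2 + 1 / (2 * h * ri))
      A[iu[i], ip[i - 1]] <- 1 / (2 * h)
      A[iu[i], ip[i + 1]] <- -1 / (2 * h)
    }
    # outer radial traction: (lambda+2mu) u'(a) + lambda (u/a + eps_z) = 0
    A[iu[N], iu[N]]     <- H_A * 3 / (2 * h) + lambda / a
    A[iu[N], iu[N - 1]] <- -H_A * 4 / (2 * h)
    A[iu[N], iu[N - 2]] <- H_A * 1 / (2 * h)
    A[iu[N], iez]       <- lambda
    # continuity (backward Euler): e + eps_z - dt k lap(p) = (e + eps_z)_old
    # axis node: e = 2 u'(0), lap p = 4 (p2 - p1)/h^2
    A[ip[1], iu[2]] <- 2 * 4 / (2 * h)
    A[ip[1], iu[3]] <- -2 * 1 / (2 * h)
    A[ip[1], iez]   <- 1
    A[ip[1], ip[1]] <- dt * k * 4 / h^2
    A[ip[1], ip[2]] <- -dt * k * 4 / h^2
    for (i in 2:(N - 1)) {
      ri <- r[i]
      # e_i = (u_{i+1}-u_{i-1})/(2h) + u_i/r_i
      A[ip[i], iu[i + 1]] <- 1 / (2 * h)
      A[ip[i], iu[i - 1]] <- -1 / (2 * h)
      A[ip[i], iu[i]]     <- 1 / ri
      A[ip[i], iez]       <- 1
      A[ip[i], ip[i - 1]] <- -dt * k * (1 / h^2 - 1 / (2 * h * ri))
      A[ip[i], ip[i]]     <- -dt * k * (-2 / h^2)
      A[ip[i], ip[i + 1]] <- -dt * k * (1 / h^2 + 1 / (2 * h * ri))
    }
    # drained boundary: p(a) = 0
    A[ip[N], ip[N]] <- 1
    # axial force: area mean of (lambda e + H_A eps_z - p) = -sigma0
    wts <- r; wts[1] <- wts[1] + h / 8; wts[N] <- wts[N] / 2  # trapezoid on f*r
    wts <- wts / sum(wts)
    for (i in 1:N) {
      if (i == 1) {
        A[iez, iu[2]] <- A[iez, iu[2]] + wts[1] * lambda * 2 * 4 / (2 * h)
        A[iez, iu[3]] <- A[iez, iu[3]] - wts[1] * lambda * 2 * 1 / (2 * h)
      } else if (i < N) {
        A[iez, iu[i + 1]] <- A[iez, iu[i + 1]] + wts[i] * lambda / (2 * h)
        A[iez, iu[i - 1]] <- A[iez, iu[i - 1]] - wts[i] * lambda / (2 * h)
        A[iez, iu[i]]     <- A[iez, iu[i]] + wts[i] * lambda / r[i]
      } else {
        A[iez, iu[N]]     <- A[iez, iu[N]] + wts[N] * lambda * 3 / (2 * h)
        A[iez, iu[N - 1]] <- A[iez, iu[N - 1]] - wts[N] * lambda * 4 / (2 * h)
        A[iez, iu[N - 2]] <- A[iez, iu[N - 2]] + wts[N] * lambda * 1 / (2 * h)
      }
      A[iez, ip[i]] <- A[iez, ip[i]] - wts[i]
      A[iez, iez]   <- A[iez, iez] + wts[i] * H_A
    }
    A
  }

  e_of <- function(x) {  # volumetric-in-plane strain at nodes from state
    u <- x[iu]
    e <- numeric(N)
    e[1] <- 2 * (4 * u[2] - u[3]) / (2 * h)
    for (i in 2:(N - 1))
      e[i] <- (u[i + 1] - u[i - 1]) / (2 * h) + u[i] / r[i]
    e[N] <- (3 * u[N] - 4 * u[N - 1] + u[N - 2]) / (2 * h) + u[N] / a
    e
  }

  x <- numeric(2 * N + 1)
  t_now <- 0
  dt <- dt0
  out <- numeric(length(t))
  j <- 1
  lu_dt <- -1; A_lu <- NULL
  while (j <= length(t)) {
    dt_use <- min(dt, t[j] - t_now)
    if (dt_use != lu_dt) {
      A_lu <- build_system(dt_use)
      lu_dt <- dt_use
    }
    rhs <- numeric(2 * N + 1)
    eo <- e_of(x)
    rhs[ip[1:(N - 1)]] <- eo[1:(N - 1)] + x[iez]
    rhs[iez] <- -sigma0
    x <- solve(A_lu, rhs)
    t_now <- t_now + dt_use
    if (abs(t_now - t[j]) < 1e-9 * max(t[j], 1)) {
      out[j] <- -x[iez]
      j <- j + 1
    }
    dt <- dt * 1.05
  }
  out
}
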