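#' Default search box for creep parameter identification
#'
#' Spans reported healthy-to-degraded cartilage ranges; `k0` is searched
#' in log10 space.
#'
#' @return Named list of `c(lower, upper)` pairs for `E_nf`, `E_f0`,
#'   `E_feps` \[MPa\], `k0` \[m^4/(N s)\] and `M`.
#' @export
default_fit_bounds <- function() {
  list(E_nf = c(0.01, 5), E_f0 = c(0, 20), E_feps = c(0, 1000),
       k0 = c(1e-16, 1e-13), M = c(0, 15))
}

#' Define a creep-curve fitting problem
#'
#' The measured quantity is the total axial displacement of the plug
#' pair; the model represents the pair as a single layer of averaged
#' thickness carrying `model_share` (default half) of the pair
#' displacement.
#'
#' @param target_time Experimental time grid \[s\].
#' @param target_displacement Experimental pair displacement \[mm\]
#'   (positive into the tissue).
#' @param geometry A [creep_geometry()] (fitting default 15 x 10 mesh).
#' @param protocol A [loading_protocol()].
#' @param bounds Search box, as [default_fit_bounds()].
#' @param n_starts Number of Latin-hypercube multi-start points.
#' @param model_share Fraction of the pair displacement assigned to the
#'   modelled layer.
#' @param fixed Named list overriding fixed constants passed to
#'   [material_params()] (`nu`, `eta_fibril`, `e0`).
#' @param time_unit Unit of `target_time` (`"s"` or `"ms"`); inputs are
#'   normalised to seconds.
#' @return A `fit_problem` list.
#' @export
fit_problem <- function(target_time, target_displacement,
                        geometry = creep_geometry(n_r = 15, n_z = 10),
                        protocol = loading_protocol(),
                        bounds = default_fit_bounds(),
                        n_starts = 8, model_share = 0.5,
                        fixed = list(), time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  if (time_unit == "ms") target_time <- target_time * 1e-3
  stopifnot(length(target_time) == length(target_displacement),
            all(diff(target_time) > 0), n_starts >= 1,
            model_share > 0, model_share <= 1)
  bt <- vapply(bounds, function(b) b[2] > b[1] && all(is.finite(b)),
               logical(1))
  stopifnot(all(bt))
  span <- log10(max(target_time) / max(protocol$ramp_duration, 1e-6))
  if (span < 3)
    warning("target series covers < 3 decades of hold time; ",
            "parameters may be poorly identified")
  structure(list(target_time = target_time,
                 target_displacement = target_displacement,
                 geometry = geometry, protocol = protocol,
                 bounds = bounds, n_starts = as.integer(n_starts),
                 model_share = model_share, fixed = fixed),
            class = "fit_problem")
}

# internal: map between the bounded physical box and unconstrained
# optimisation coordinates. Moduli and permeability are searched in
# log10 space (their plausible ranges span decades); a logit wraps each
# log-range into an unconstrained coordinate. Zero lower bounds on the
# fibril moduli are floored at 1e-3 MPa (numerically indistinguishable
# from a fibril-free response at tissue scale).
fit_log_box <- function(b, floor_ = 1e-3) log10(c(max(b[1], floor_), b[2]))

fit_to_z <- function(theta, bounds) {
  f <- function(v, b) {
    u <- (v - b[1]) / (b[2] - b[1])
    u <- min(max(u, 1e-9), 1 - 1e-9)
    log(u / (1 - u))
  }
  c(f(log10(max(theta[["E_nf"]], 1e-12)), fit_log_box(bounds$E_nf)),
    f(log10(max(theta[["E_f0"]], 1e-12)), fit_log_box(bounds$E_f0)),
    f(log10(max(theta[["E_feps"]], 1e-12)), fit_log_box(bounds$E_feps)),
    f(log10(theta[["k0"]]), log10(bounds$k0)),
    f(theta[["M"]], bounds$M))
}

fit_from_z <- function(z, bounds) {
  g <- function(zi, b) b[1] + (b[2] - b[1]) / (1 + exp(-zi))
  list(E_nf = 10^g(z[1], fit_log_box(bounds$E_nf)),
       E_f0 = 10^g(z[2], fit_log_box(bounds$E_f0)),
       E_feps = 10^g(z[3], fit_log_box(bounds$E_feps)),
       k0 = 10^g(z[4], log10(bounds$k0)),
       M = g(z[5], bounds$M))
}

# internal: residual vector (and RMSE) between simulated layer
# displacement and the share of the measured pair displacement
fit_residuals <- function(theta, problem, opts) {
  params <- do.call(material_params, c(theta, problem$fixed))
  pr <- problem$protocol
  ot <- problem$target_time
  ot <- ot[ot > 0 & ot <= pr$hold_duration]
  prot <- loading_protocol(pr$applied_stress, pr$ramp_duration,
                           pr$hold_duration, output_times = ot)
  sol <- run_creep(params, problem$geometry, prot, opts)
  target <- problem$model_share *
    problem$target_displacement[problem$target_time %in% ot]
  sol$displacement - target
}

fit_cost <- function(theta, problem, opts) {
  sqrt(mean(fit_residuals(theta, problem, opts)^2))
}

#' Identify material parameters from a creep curve
#'
#' Minimises the root-mean-square error between the measured axial creep
#' displacement (scaled by `model_share`) and the simulated layer
#' displacement over the five free parameters. Every Latin-hypercube
#' start is screened with one evaluation; the best are refined by
#' bounded damped least squares (Levenberg-Marquardt on the residual
#' vector, in logit/log-transformed coordinates so moduli and
#' permeability are searched across decades). Uniqueness is assessed
#' from the per-start table.
#'
#' @param problem A [fit_problem()].
#' @param opts [solver_options()] used during optimisation (fitting
#'   default: relaxed stepping on the coarse mesh).
#' @param max_eval Evaluation cap per refined start.
#' @param n_refine Number of best-screened starts refined by
#'   Nelder-Mead (the remaining Latin-hypercube points contribute their
#'   screening evaluation to the per-start table).
#' @param rmse_tol Stop early once a start reaches this RMSE \[mm\].
#' @param seed Seed for the Latin-hypercube draw.
#' @param verbose Print per-start progress.
#' @return A `fit_result`: best-fit [material_params()], `rmse` \[mm\],
#'   `r_squared` of model vs (scaled) experiment, the per-start table,
#'   and a `converged` flag (TRUE if any start converged).
#' @export
fit_parameters <- function(problem,
                           opts = solver_options(newton_tol = 1e-5,
                                                 dt0 = 0.1,
                                                 dt_growth = 1.6,
                                                 dt_max = 500,
                                                 max_halvings = 8,
                                                 max_steps = 1000),
                           max_eval = 400, n_refine = 2, rmse_tol = 1e-5,
                           seed = 1, verbose = FALSE) {
  stopifnot(inherits(problem, "fit_problem"))
  b <- problem$bounds
  ns <- problem$n_starts
  set.seed(seed)
  u01 <- lhs::randomLHS(ns, 5)
  # keep LHS starts away from the extreme logit tails
  u01 <- 0.05 + 0.9 * u01
  starts <- log(u01 / (1 - u01))

  n_eval <- 0L
  cost_z <- function(z) {
    n_eval <<- n_eval + 1L
    theta <- fit_from_z(z, b)
    out <- tryCatch(fit_cost(theta, problem, opts), error = function(e) NA)
    if (!is.finite(out)) 1e6 else out
  }

  # stage 1: screen every Latin-hypercube point
  screen <- vapply(seq_len(ns), function(s) cost_z(starts[s, ]),
                   numeric(1))
  refine_order <- order(screen)[seq_len(min(n_refine, ns))]

  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    th <- fit_from_z(starts[s, ], b)
    rows[[s]] <- data.frame(start = s, converged = screen[s] < 1e6,
                            refined = FALSE, rmse = screen[s],
                            E_nf = th$E_nf, E_f0 = th$E_f0,
                            E_feps = th$E_feps, k0 = th$k0, M = th$M,
                            n_eval = 1L)
  }

  # stage 2: damped least-squares refinement from the best-screened
  # starts. The objective is a smooth nonlinear least-squares problem,
  # so Levenberg-Marquardt on the residual vector (finite-difference
  # Jacobian, 5 extra simulations per iteration) descends the strongly
  # correlated fibril-stiffness valley that defeats simplex search.
  last_res <- NULL
  resid_z <- function(z) {
    # hard evaluation cap: once spent, echo the last residual so the
    # optimiser sees no further improvement and terminates
    if (n_eval >= max_eval && !is.null(last_res)) return(last_res)
    n_eval <<- n_eval + 1L
    theta <- fit_from_z(z, b)
    out <- tryCatch(fit_residuals(theta, problem, opts),
                    error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out)))
      out <- rep(1e3, length(problem$target_time))
    last_res <<- out
    out
  }
  best <- NULL
  for (s in refine_order) {
    n_eval <- 0L
    last_res <- NULL
    fit <- tryCatch({
      lmf <- minpack.lm::nls.lm(
        starts[s, ], fn = resid_z,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000L, ftol = max((rmse_tol / 10)^2, 1e-14),
          ptol = 1e-10, epsfcn = 1e-8))
      list(par = lmf$par, value = sqrt(mean(lmf$fvec^2)),
           hessian = lmf$hessian, n_res = length(lmf$fvec))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e3) {
      rows[[s]]$converged <- FALSE
      next
    }
    th <- fit_from_z(fit$par, b)
    rows[[s]] <- data.frame(start = s, converged = TRUE, refined = TRUE,
                            rmse = fit$value, E_nf = th$E_nf,
                            E_f0 = th$E_f0, E_feps = th$E_feps,
                            k0 = th$k0, M = th$M, n_eval = n_eval)
    if (verbose)
      message(sprintf("start %d refined: rmse %.3g mm after %d evals",
                      s, fit$value, n_eval))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$value < rmse_tol) break
  }
  per_start <- do.call(rbind, rows)
  if (is.null(best)) stop("all optimisation starts failed")

  th <- fit_from_z(best$par, b)
  params <- do.call(material_params, c(th, problem$fixed))
  # recompute the best fit for the reported curve and R^2
  pr <- problem$protocol
  ot <- problem$target_time
  ot <- ot[ot > 0 & ot <= pr$hold_duration]
  prot <- loading_protocol(pr$applied_stress, pr$ramp_duration,
                           pr$hold_duration, output_times = ot)
  sol <- run_creep(params, problem$geometry, prot, opts)
  target <- problem$model_share *
    problem$target_displacement[problem$target_time %in% ot]
  rmse <- sqrt(mean((sol$displacement - target)^2))
  r2 <- 1 - sum((sol$displacement - target)^2) /
    sum((target - mean(target))^2)
  # Gauss-Newton parameter covariance in the transformed coordinates:
  # sigma^2 (J'J)^-1 from the best start's final Jacobian (pseudo-
  # inverse over the numerically identified directions)
  vcov_z <- NULL
  if (!is.null(best$hessian)) {
    s2 <- best$value^2 * best$n_res / max(best$n_res - 5, 1)
    sv <- svd(best$hessian)
    pos <- sv$d > max(sv$d) * 1e-10
    vcov_z <- s2 * sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  structure(list(params = params, rmse = rmse, r_squared = r2,
                 per_start = per_start, converged = any(per_start$converged),
                 best_curve = data.frame(time = ot,
                                         model = sol$displacement,
                                         target = target),
                 z_hat = best$par, vcov_z = vcov_z,
                 problem = problem),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Creep fit: RMSE %.4g mm, R^2 %.4f (%d/%d starts converged)\n",
              x$rmse, x$r_squared, sum(x$per_start$converged),
              nrow(x$per_start)))
  print(x$params)
  invisible(x)
}

#' Write a fit result to JSON (+ per-start CSV)
#'
#' @param fit A `fit_result`.
#' @param path JSON output path; the per-start table is written next to
#'   it with suffix `_starts.csv`.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  p <- fit$params
  jsonlite::write_json(list(
    params = list(E_nf_MPa = p$E_nf, E_f0_MPa = p$E_f0,
                  E_feps_MPa = p$E_feps, k0_m4_per_Ns = p$k0, M = p$M,
                  nu = p$nu, eta_fibril_MPa_s = p$eta_fibril, e0 = p$e0),
    rmse_mm = fit$rmse, r_squared = fit$r_squared),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$per_start,
                   sub("\\.json$", "_starts.csv", path), row.names = FALSE)
  invisible(path)
}

#' Draw parameter sets from the fit's Gauss-Newton uncertainty
#'
#' Samples material-parameter sets from the normal approximation to the
#' fit uncertainty (the damped-least-squares covariance in the
#' transformed search coordinates), for propagating identification
#' uncertainty into downstream quantities such as the modelled IFLS.
#'
#' @param fit A `fit_result` from [fit_parameters()].
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return List of [material_params()].
#' @export
sample_fit_params <- function(fit, n = 10, seed = 1) {
  stopifnot(inherits(fit, "fit_result"), !is.null(fit$vcov_z))
  set.seed(seed)
  ev <- eigen(fit$vcov_z, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 5)
  b <- fit$problem$bounds
  lapply(seq_len(n), function(i) {
    z <- fit$z_hat + as.numeric(L %*% rnorm(5))
    do.call(material_params,
            c(fit_from_z(z, b), fit$problem$fixed))
  })
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the creep simulation varying a single constitutive parameter
#' (all others held fixed), e.g. the nonfibrillar Poisson's ratio over
#' {0.15, 0.37, 0.47}.
#'
#' @param params Baseline [material_params()].
#' @param geometry,protocol,opts As in [run_creep()].
#' @param param_name One of the [material_params()] field names.
#' @param values Values to sweep.
#' @return Named list of `creep_solution` objects (names are the
#'   values).
#' @export
sensitivity_sweep <- function(params, geometry, protocol, param_name,
                              values, opts = solver_options()) {
  stopifnot(inherits(params, "material_params"),
            param_name %in% names(params))
  out <- lapply(values, function(v) {
    p <- unclass(params)
    p[[param_name]] <- v
    run_creep(do.call(material_params, p), geometry, protocol, opts)
  })
  names(out) <- as.character(values)
  out
}
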