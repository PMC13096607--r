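#' Solver options for the creep finite-element model
#'
#' @param newton_tol Relative Newton tolerance (residuals scaled by the
#'   applied load and the step's initial continuity residual).
#' @param newton_maxit Maximum Newton iterations per time step.
#' @param n_ramp_steps Time steps across the load ramp.
#' @param dt0 Initial post-ramp step \[s\].
#' @param dt_growth Geometric step growth factor.
#' @param dt_max Maximum step \[s\].
#' @param stab_alpha Magnitude of the local pressure-projection
#'   stabilisation of the equal-order u/p pair (dimensionless; 0
#'   disables).
#' @param small_strain Use linearised kinematics (verification against
#'   the linear biphasic oracle only).
#' @param bottom_radial_slip Allow frictionless radial slip at the
#'   cartilage-bone interface instead of the physical fully-fixed
#'   condition (used only to match the frictionless-platen assumption of
#'   the closed-form biphasic oracle).
#' @param max_halvings Maximum time-step halvings on Newton failure.
#' @param max_steps Abort (with an error) if the simulation needs more
#'   than this many time steps; fitting loops use a low cap so
#'   pathological parameter candidates fail fast.
#' @param store_fields Keep nodal pore-pressure snapshots at the output
#'   times.
#' @return A `solver_options` list.
#' @export
solver_options <- function(newton_tol = 1e-7, newton_maxit = 30,
                           n_ramp_steps = 8, dt0 = 0.05, dt_growth = 1.15,
                           dt_max = 250, stab_alpha = 0.05,
                           small_strain = FALSE, bottom_radial_slip = FALSE,
                           max_halvings = 25, max_steps = 100000,
                           store_fields = FALSE) {
  structure(as.list(environment()), class = "solver_options")
}

# Pack mesh + dof numbering + material into the list the C++ core expects.
# Internally SI: nodes in m, stresses in Pa, permeability m^4/(N s).
fem_prepare <- function(mesh, params, opts,
                        layout = fibril_network_layout()) {
  g <- mesh$geometry
  n_r <- g$n_r; n_z <- g$n_z
  nn <- nrow(mesh$nodes)
  i_of <- rep(0:n_r, each = n_z + 1)
  j_of <- rep(0:n_z, times = n_r + 1)
  dof_ur <- integer(nn); dof_uz <- integer(nn); dof_p <- integer(nn)
  nd <- 0L
  for (n in seq_len(nn)) {
    i <- i_of[n]; j <- j_of[n]
    ur_free <- i > 0 && (j > 0 || isTRUE(opts$bottom_radial_slip))
    if (ur_free) { dof_ur[n] <- nd; nd <- nd + 1L } else dof_ur[n] <- -1L
    if (j == 0) dof_uz[n] <- -1L
    else if (j == n_z) dof_uz[n] <- -2L
    else { dof_uz[n] <- nd; nd <- nd + 1L }
    if (i == n_r) dof_p[n] <- -1L else { dof_p[n] <- nd; nd <- nd + 1L }
  }
  conn0 <- mesh$elems - 1L
  bw <- 0L
  for (e in seq_len(nrow(conn0))) {
    ids <- c(dof_ur[conn0[e, ] + 1L], dof_uz[conn0[e, ] + 1L],
             dof_p[conn0[e, ] + 1L])
    ids <- ids[ids >= 0L]
    if (length(ids) > 1) bw <- max(bw, max(ids) - min(ids))
  }
  list(nodes_m = mesh$nodes * 1e-3,
       conn0 = conn0,
       dof_ur = dof_ur, dof_uz = dof_uz, dof_p = dof_p,
       n_dof = nd, bw = bw,
       dirs = layout$directions, dir_wts = layout$weights,
       stab_alpha = opts$stab_alpha,
       small_strain = as.integer(opts$small_strain),
       mat_si = list(E_nf = params$E_nf * 1e6, nu = params$nu,
                     E_f0 = params$E_f0 * 1e6,
                     E_feps = params$E_feps * 1e6,
                     eta = params$eta_fibril * 1e6,
                     k0 = params$k0, M = params$M))
}

# Area-weighted average pore pressure over the platen contact surface
# (exact integral of the nodal-linear pressure over the deformed face).
surface_por <- function(fem, mesh, x) {
  top <- mesh$top_nodes
  p <- ifelse(fem$dof_p[top] >= 0, x[fem$dof_p[top] + 1L], 0)
  r <- fem$nodes_m[top, 1] +
    ifelse(fem$dof_ur[top] >= 0, x[fem$dof_ur[top] + 1L], 0)
  num <- 0; den <- 0
  for (s in seq_len(length(top) - 1)) {
    r0 <- r[s]; r1 <- r[s + 1]; p0 <- p[s]; p1 <- p[s + 1]
    dr <- r1 - r0
    num <- num + dr * (2 * p0 * r0 + p0 * r1 + p1 * r0 + 2 * p1 * r1) / 6
    den <- den + dr * (r0 + r1) / 2
  }
  num / den
}

# Volume-average pore pressure over the (reference) model domain:
# 2x2 Gauss quadrature of the bilinear pressure field with the
# axisymmetric radial weight. This is the default POR definition: it
# reads "average pore pressure extracted from the model" literally and
# reproduces the printed strain-IFLS regressions (see vignette).
volume_por <- function(fem, mesh, x) {
  p <- ifelse(fem$dof_p >= 0, x[fem$dof_p + 1L], 0)
  el <- mesh$elems
  g <- 0.5773502691896258
  num <- 0; den <- 0
  for (gp in list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))) {
    N <- 0.25 * c((1 - gp[1]) * (1 - gp[2]), (1 + gp[1]) * (1 - gp[2]),
                  (1 + gp[1]) * (1 + gp[2]), (1 - gp[1]) * (1 + gp[2]))
    rg <- as.numeric(matrix(fem$nodes_m[el, 1], nrow(el), 4) %*% N)
    pg <- as.numeric(matrix(p[el], nrow(el), 4) %*% N)
    num <- num + sum(pg * rg)
    den <- den + sum(rg)
  }
  num / den
}

#' Run the unconfined creep simulation
#'
#' Solves the coupled finite-strain Biot equations for an axisymmetric
#' cartilage layer under a constant axial load applied through an
#' impermeable rigid frictionless platen: total stress is the sum of the
#' tension-only viscoelastic fibril network stress and the Neo-Hookean
#' nonfibrillar matrix stress minus pore pressure; Darcy flow with
#' deformation-dependent permeability; backward-Euler time stepping with
#' Newton iteration and adaptive step halving. Boundary conditions:
#' cartilage-bone interface fixed and impermeable, outer edge free and
#' fully permeable (p = 0), symmetry axis impermeable with no radial
#' motion, platen impermeable with all contact nodes sharing one axial
#' degree of freedom and free radial slip.
#'
#' @param params A [material_params()].
#' @param geometry A [creep_geometry()].
#' @param protocol A [loading_protocol()].
#' @param opts A [solver_options()].
#' @param layout A [fibril_network_layout()].
#' @param por_method `"volume"` (average pore pressure over the model
#'   domain, default) or `"surface"` (area-weighted average over the
#'   platen contact face).
#' @return A `creep_solution`: data frame with columns `time` \[s\],
#'   `displacement` \[mm, positive into the tissue\], `strain`
#'   (displacement / thickness), `POR` \[MPa\], `IFLS` (= POR / applied
#'   stress) and `reaction` \[N\], with the inputs and optional pressure
#'   field snapshots as attributes.
#' @export
#' @examples
#' \donttest{
#' p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
#'                      k0 = 2e-15, M = 5)
#' sol <- run_creep(p, creep_geometry(thickness = 1.7, n_r = 15, n_z = 10),
#'                  loading_protocol(hold_duration = 100))
#' head(as.data.frame(sol))
#' }
run_creep <- function(params, geometry, protocol,
                      opts = solver_options(),
                      layout = fibril_network_layout(),
                      por_method = c("volume", "surface")) {
  stopifnot(inherits(params, "material_params"),
            inherits(geometry, "creep_geometry"),
            inherits(protocol, "loading_protocol"))
  por_method <- match.arg(por_method)
  mesh <- build_mesh(geometry)
  fem <- fem_prepare(mesh, params, opts, layout)
  ndir <- nrow(layout$directions)
  W <- protocol$applied_stress * 1e6 * pi * (geometry$radius * 1e-3)^2  # N
  Fext_at <- function(t) -W * min(t / protocol$ramp_duration, 1)

  x <- numeric(fem$n_dof + 1L)
  q <- numeric(nrow(mesh$elems) * 4L * ndir)
  t_now <- 0
  T_end <- protocol$hold_duration

  rec_t <- 0; rec_u <- 0; rec_por <- 0; rec_f <- 0
  fields <- if (opts$store_fields) list(`0` = x) else NULL

  dt_ramp <- protocol$ramp_duration / opts$n_ramp_steps
  dt_plan <- dt_ramp
  dt_next_growth <- opts$dt0
  n_steps <- 0L

  while (t_now < T_end - 1e-9) {
    n_steps <- n_steps + 1L
    if (n_steps > opts$max_steps)
      stop("creep solver aborted: more than ", opts$max_steps,
           " time steps needed (step-halving cascade)")
    in_ramp <- t_now < protocol$ramp_duration - 1e-12
    dt <- if (in_ramp) min(dt_plan, protocol$ramp_duration - t_now)
          else min(dt_plan, T_end - t_now)
    halved <- 0
    repeat {
      st <- fe_newton_step(x, x, q, dt, Fext_at(t_now + dt), fem,
                           opts$newton_tol, 1e-12, opts$newton_maxit)
      if (isTRUE(st$converged)) break
      halved <- halved + 1
      if (halved > opts$max_halvings)
        stop("creep solver failed: Newton did not converge at t = ",
             signif(t_now, 4), " s (dt = ", signif(dt, 3), " s)")
      dt <- dt / 2
    }
    x <- st$x; q <- st$q
    t_now <- t_now + dt
    rec_t <- c(rec_t, t_now)
    rec_u <- c(rec_u, -x[fem$n_dof + 1L])
    rec_por <- c(rec_por, if (por_method == "surface")
      surface_por(fem, mesh, x) else volume_por(fem, mesh, x))
    rec_f <- c(rec_f, -st$f_int_platen)
    if (opts$store_fields) fields[[sprintf("%.6g", t_now)]] <- x
    if (in_ramp) {
      dt_plan <- dt_ramp
      if (t_now >= protocol$ramp_duration - 1e-12) dt_plan <- dt_next_growth
    } else {
      dt_plan <- min(max(dt * opts$dt_growth, dt), opts$dt_max)
    }
  }

  ot <- protocol$output_times
  out <- data.frame(
    time = ot,
    displacement = stats::approx(rec_t, rec_u, ot, rule = 2)$y * 1e3,
    POR = stats::approx(rec_t, rec_por, ot, rule = 2)$y * 1e-6,
    reaction = stats::approx(rec_t, rec_f, ot, rule = 2)$y)
  out$strain <- out$displacement / geometry$thickness
  out$IFLS <- out$POR / protocol$applied_stress
  out <- out[, c("time", "displacement", "strain", "POR", "IFLS",
                 "reaction")]
  structure(out,
            class = c("creep_solution", "data.frame"),
            params = params, geometry = geometry, protocol = protocol,
            opts = opts, por_method = por_method,
            steps = data.frame(time = rec_t, displacement = rec_u * 1e3,
                               POR = rec_por * 1e-6, reaction = rec_f),
            fields = fields, fem = fem, mesh = mesh,
            final_state = list(x = x, q = q))
}

#' @export
print.creep_solution <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf(paste0("Unconfined creep solution: %d output times to %g s",
                     " under %g MPa\n"),
              nrow(x), max(x$time), pr$applied_stress))
  n <- nrow(x)
  cat(sprintf("  final displacement %.4g mm (strain %.3g), IFLS %.3g\n",
              x$displacement[n], x$strain[n], x$IFLS[n]))
  invisible(x)
}

#' Export a creep solution as tidy CSV
#'
#' @param sol A `creep_solution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_creep_solution <- function(sol, path) {
  stopifnot(inherits(sol, "creep_solution"))
  utils::write.csv(as.data.frame(sol), path, row.names = FALSE)
  invisible(path)
}

#' Continue a creep simulation until displacement-rate equilibrium
#'
#' Runs [run_creep()] and, if the displacement rate at the end of the
#' hold still exceeds `rate_tol`, extends the hold (doubling the
#' duration) until it does not.
#'
#' @param params,geometry,protocol,opts,layout,por_method As in
#'   [run_creep()].
#' @param rate_tol Displacement-rate threshold \[m/s\] (default 1e-9).
#' @param max_extend Maximum number of hold doublings.
#' @return A `creep_solution` whose final time satisfies the rate
#'   criterion.
#' @export
run_creep_to_equilibrium <- function(params, geometry, protocol,
                                     opts = solver_options(),
                                     layout = fibril_network_layout(),
                                     por_method = "volume",
                                     rate_tol = 1e-9, max_extend = 6) {
  for (i in 0:max_extend) {
    sol <- run_creep(params, geometry, protocol, opts, layout, por_method)
    stp <- attr(sol, "steps")
    n <- nrow(stp)
    rate <- abs(stp$displacement[n] - stp$displacement[n - 1]) * 1e-3 /
      (stp$time[n] - stp$time[n - 1])
    if (rate < rate_tol) return(sol)
    protocol <- loading_protocol(protocol$applied_stress,
                                 protocol$ramp_duration,
                                 protocol$hold_duration * 2)
  }
  warning("displacement-rate criterion not reached; returning last run")
  sol
}
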