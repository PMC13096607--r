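#' Specification of one synthetic experimental group
#'
#' Defines the distributions a synthetic group is drawn from: log-normal
#' per-parameter scatter around median material parameters, a
#' ground-truth friction law `mu = mu_IFLS * IFLS + mu_0 (+ quad *
#' IFLS^2)`, instrument noise levels, and the thickness distribution.
#' Degraded groups are softer and more permeable (about a threefold
#' change) and carry a small quadratic friction term reproducing the
#' extra nonlinearity seen in degraded tissue.
#'
#' @param group Group label.
#' @param median_params [material_params()] medians.
#' @param dispersion Log-normal sdlog applied to each of the five free
#'   parameters (scalar or named vector).
#' @param friction_law List `mu_ifls`, `mu_0`, `quad`.
#' @param noise List `disp_um` (displacement noise sd, micrometres),
#'   `torque_Nm` (torque noise sd), `force_N` (force noise sd).
#' @param thickness List `median` \[mm\] and `sdlog` for per-plug
#'   thickness draws.
#' @return A `group_spec`.
#' @export
group_spec <- function(group, median_params, dispersion = 0.25,
                       friction_law = list(mu_ifls = -0.15, mu_0 = 0.11,
                                           quad = 0),
                       noise = list(disp_um = 2, torque_Nm = 2e-4,
                                    force_N = 0.05),
                       thickness = list(median = 1.7, sdlog = 0.15)) {
  stopifnot(inherits(median_params, "material_params"),
            all(unlist(noise) >= 0), thickness$median > 0)
  if (length(dispersion) == 1)
    dispersion <- setNames(rep(dispersion, 5),
                           c("E_nf", "E_f0", "E_feps", "k0", "M"))
  structure(list(group = group, median_params = median_params,
                 dispersion = dispersion, friction_law = friction_law,
                 noise = noise, thickness = thickness),
            class = "group_spec")
}

#' Default specifications of the four experimental groups
#'
#' Healthy and enzymatically degraded plugs in saline or bovine synovial
#' fluid. Healthy medians are typical bovine femoral-condyle values for
#' this model family; degraded medians are softened threefold with
#' threefold-increased initial permeability. Ground-truth friction laws
#' follow the per-group regression scale of the study (healthy-saline
#' uses slope -0.15, intercept 0.11); degraded groups add a quadratic
#' IFLS term (+0.03).
#'
#' @return Named list of four [group_spec()] objects.
#' @export
default_group_specs <- function() {
  healthy <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
                             k0 = 2e-15, M = 5)
  degraded <- material_params(E_nf = 0.1, E_f0 = 0.67, E_feps = 33,
                              k0 = 6e-15, M = 5)
  list(
    "healthy-saline" = group_spec(
      "healthy-saline", healthy,
      friction_law = list(mu_ifls = -0.15, mu_0 = 0.11, quad = 0)),
    "healthy-BSF" = group_spec(
      "healthy-BSF", healthy,
      friction_law = list(mu_ifls = -0.08, mu_0 = 0.07, quad = 0)),
    "degraded-saline" = group_spec(
      "degraded-saline", degraded,
      friction_law = list(mu_ifls = -0.08, mu_0 = 0.05, quad = 0.03),
      thickness = list(median = 2.1, sdlog = 0.15)),
    "degraded-BSF" = group_spec(
      "degraded-BSF", degraded,
      friction_law = list(mu_ifls = -0.04, mu_0 = 0.04, quad = 0.03),
      thickness = list(median = 2.1, sdlog = 0.15)))
}

#' Draw material parameters and thicknesses for a synthetic group
#'
#' Log-normal draws centred (median) on the group's parameters; draws
#' falling outside the fitting bounds are redrawn (at most 100
#' attempts each).
#'
#' @param spec A [group_spec()].
#' @param n Number of specimen pairs.
#' @param seed RNG seed.
#' @param bounds Admissible box, as [default_fit_bounds()].
#' @return List with `params` (list of [material_params()]) and
#'   `thicknesses` (n x 2 matrix \[mm\]).
#' @export
sample_group_params <- function(spec, n, seed = 1,
                                bounds = default_fit_bounds()) {
  stopifnot(inherits(spec, "group_spec"), n >= 1)
  set.seed(seed)
  med <- spec$median_params
  free <- c("E_nf", "E_f0", "E_feps", "k0", "M")
  draws <- matrix(NA_real_, n, 5, dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    f <- free[j]
    sdl <- spec$dispersion[[f]]
    for (i in seq_len(n)) {
      for (attempt in 1:100) {
        v <- if (sdl == 0) med[[f]] else
          rlnorm(1, meanlog = log(med[[f]]), sdlog = sdl)
        if (v >= bounds[[f]][1] && v <= bounds[[f]][2]) break
        v <- NA
      }
      if (is.na(v)) stop("could not draw ", f, " within bounds")
      draws[i, j] <- v
    }
  }
  th <- matrix(rlnorm(2 * n, log(spec$thickness$median),
                      spec$thickness$sdlog), n, 2)
  params <- lapply(seq_len(n), function(i)
    material_params(E_nf = unname(draws[i, "E_nf"]),
                    E_f0 = unname(draws[i, "E_f0"]),
                    E_feps = unname(draws[i, "E_feps"]),
                    k0 = unname(draws[i, "k0"]),
                    M = unname(draws[i, "M"]), nu = med$nu,
                    eta_fibril = med$eta_fibril, e0 = med$e0))
  list(params = params, thicknesses = th)
}

# rotation-block length [s] for a velocity: the protocol applies
# alternating +/-6-revolution rotations in blocks of 18, 124, 180 and
# 516 rotations at 36, 108, 360 and 1080 deg/s, each followed by a 10 s
# lift-off; other velocities get a block of comparable duration.
rotation_block_s <- function(omega) {
  std <- c(`36` = 18, `108` = 124, `360` = 180, `1080` = 516)
  key <- as.character(omega)
  n_rot <- if (key %in% names(std)) std[[key]]
           else max(1, round(175 * omega / 360))
  n_rot * 360 / omega
}

#' Synthesise one tribology record with known ground truth
#'
#' Forward-simulates the creep of the pair ([run_creep()], coarse mesh
#' by default), then builds 10-Hz signals: axial force at the nominal
#' load (dropping to near zero during the 10-s lift-offs inserted after
#' each rotation block), pair displacement as twice the modelled layer
#' displacement, and torque obtained by inverting the friction formula
#' so that `compute_cof` recovers the group's ground-truth law
#' evaluated at the simulated IFLS. Gaussian instrument noise per the
#' group spec.
#'
#' @param params [material_params()] ground truth for this pair.
#' @param thicknesses Length-2 plug thicknesses \[mm\].
#' @param spec The pair's [group_spec()].
#' @param omega Angular velocity \[deg/s\].
#' @param protocol A [loading_protocol()].
#' @param seed RNG seed for the noise streams.
#' @param geometry Mesh for the forward simulation (coarse default).
#' @param opts [solver_options()].
#' @param liftoffs Insert lift-off events (default TRUE).
#' @param rate_hz Sampling rate (default 10).
#' @param model_share Fraction of pair displacement carried by the
#'   modelled layer (default 0.5).
#' @return A `synthetic_experiment`: `record`
#'   ([tribology_record()]), `truth` (params, friction law, IFLS/strain
#'   series), and `seed`.
#' @export
synthesize_record <- function(params, thicknesses, spec, omega,
                              protocol = loading_protocol(),
                              seed = 1,
                              geometry = NULL,
                              opts = solver_options(newton_tol = 1e-6,
                                                    dt0 = 0.1,
                                                    dt_growth = 1.35,
                                                    dt_max = 500),
                              liftoffs = TRUE, rate_hz = 10,
                              model_share = 0.5) {
  stopifnot(inherits(spec, "group_spec"), length(thicknesses) == 2)
  if (is.null(geometry))
    geometry <- creep_geometry(thickness = mean(thicknesses),
                               n_r = 15, n_z = 10)
  sol <- tryCatch(run_creep(params, geometry, protocol, opts),
                  error = function(e)
                    stop("forward simulation failed for E_nf=",
                         signif(params$E_nf, 3), ", k0=",
                         signif(params$k0, 3), ": ",
                         conditionMessage(e)))
  set.seed(seed)
  tgrid <- seq(1 / rate_hz, protocol$hold_duration, by = 1 / rate_hz)
  mi <- compute_ifls_series(sol, tgrid)
  law <- spec$friction_law
  mu_lin <- law$mu_ifls * mi$IFLS + law$mu_0 +
    (if (is.null(law$quad)) 0 else law$quad) * mi$IFLS^2
  # the linear law extrapolates below zero at very high fluid load
  # support; physical friction cannot be negative, so the generated
  # coefficient is floored at zero (the `clamped` flag marks samples
  # outside the linear regime of the generating law)
  mu_true <- pmax(mu_lin, 0)
  clamped <- mu_lin < 0
  r_m <- geometry$radius * 1e-3
  W <- protocol$applied_stress * 1e6 * pi * r_m^2

  lifted <- rep(FALSE, length(tgrid))
  if (liftoffs) {
    block <- rotation_block_s(omega)
    t0 <- protocol$ramp_duration + block
    while (t0 + 10 < max(tgrid)) {
      lifted[tgrid > t0 & tgrid <= t0 + 10] <- TRUE
      t0 <- t0 + block + 10
    }
  }
  force <- W + rnorm(length(tgrid), 0, spec$noise$force_N)
  force[lifted] <- abs(rnorm(sum(lifted), 0.5, spec$noise$force_N))
  disp <- stats::approx(attr(sol, "steps")$time,
                        attr(sol, "steps")$displacement,
                        tgrid, rule = 2)$y / model_share +
    rnorm(length(tgrid), 0, spec$noise$disp_um * 1e-3)
  torque <- (2 / 3) * r_m * force * mu_true +
    rnorm(length(tgrid), 0, spec$noise$torque_Nm)
  torque[lifted] <- rnorm(sum(lifted), 0, spec$noise$torque_Nm)

  lub <- if (grepl("BSF", spec$group)) list(name = "BSF", viscosity = 3.5)
         else list(name = "saline", viscosity = 0.9)
  rec <- tribology_record(tgrid, force, disp, torque,
                          plug_radius = geometry$radius,
                          pair_thicknesses = thicknesses,
                          angular_velocity = omega, lubricant = lub,
                          group = spec$group,
                          applied_stress = protocol$applied_stress)
  structure(list(record = rec,
                 truth = list(params = params, friction_law = law,
                              ifls = mi$IFLS, strain = mi$strain,
                              mu_true = mu_true, clamped = clamped,
                              solution = sol, lifted = lifted),
                 seed = seed),
            class = "synthetic_experiment")
}

#' Write a complete synthetic fixture set
#'
#' Generates the full study layout: `n_pairs` specimen pairs per group,
#' each tested at every angular velocity (default 3 pairs x 4 groups x 4
#' velocities = 48 records), written as CSV + metadata JSON plus a
#' ground-truth manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; per-record substreams are derived
#'   deterministically from it.
#' @param specs Group specifications ([default_group_specs()]).
#' @param n_pairs Pairs per group (default 3).
#' @param velocities Angular velocities \[deg/s\].
#' @param protocol,geometry,opts Forwarded to [synthesize_record()].
#' @param liftoffs Insert lift-offs.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
write_fixture_set <- function(out_dir, seed = 1,
                              specs = default_group_specs(),
                              n_pairs = 3,
                              velocities = c(36, 108, 360, 1080),
                              protocol = loading_protocol(),
                              geometry = NULL, opts = NULL,
                              liftoffs = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, records = list())
  k <- 0L
  for (g in names(specs)) {
    sub <- (seed * 10007L + match(g, names(specs))) %% .Machine$integer.max
    draws <- sample_group_params(specs[[g]], n_pairs, seed = sub)
    for (i in seq_len(n_pairs)) {
      for (om in velocities) {
        k <- k + 1L
        rec_seed <- (seed * 20011L + k) %% .Machine$integer.max
        args <- list(params = draws$params[[i]],
                     thicknesses = draws$thicknesses[i, ],
                     spec = specs[[g]], omega = om,
                     protocol = protocol, seed = rec_seed,
                     liftoffs = liftoffs)
        if (!is.null(geometry)) args$geometry <- geometry
        if (!is.null(opts)) args$opts <- opts
        syn <- do.call(synthesize_record, args)
        fname <- sprintf("%s_pair%d_w%04d.csv", g, i, om)
        write_tribology_record(syn$record, file.path(out_dir, fname))
        p <- syn$truth$params
        manifest$records[[length(manifest$records) + 1L]] <- list(
          file = fname, group = g, pair = i, omega = om,
          seed = rec_seed,
          truth_params = list(E_nf = p$E_nf, E_f0 = p$E_f0,
                              E_feps = p$E_feps, k0 = p$k0, M = p$M),
          truth_law = syn$truth$friction_law,
          thicknesses = as.numeric(draws$thicknesses[i, ]))
      }
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
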