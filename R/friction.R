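#' One tribo-rheometer experiment record
#'
#' Raw 10-Hz signals from a bi-axial torsional friction test on a pair of
#' coaxially aligned osteochondral plugs under constant nominal
#' compressive stress, plus the metadata needed by the pipeline.
#'
#' @param time Time \[s\], uniformly sampled.
#' @param axial_force Axial force \[N\].
#' @param axial_disp Axial pair displacement \[mm\].
#' @param torque Torque \[N m\].
#' @param plug_radius Plug radius \[mm\].
#' @param pair_thicknesses Length-2 vector, cartilage thicknesses of the
#'   two plugs \[mm\].
#' @param angular_velocity Angular velocity \[deg/s\].
#' @param lubricant List with `name` and `viscosity` \[mPa s\] (e.g.
#'   bovine synovial fluid 3.5, saline 0.9).
#' @param group One of `"healthy-saline"`, `"healthy-BSF"`,
#'   `"degraded-saline"`, `"degraded-BSF"`.
#' @param applied_stress Nominal compressive stress \[MPa\].
#' @return A `tribology_record`.
#' @export
tribology_record <- function(time, axial_force, axial_disp, torque,
                             plug_radius = 3.5,
                             pair_thicknesses = c(1.7, 1.7),
                             angular_velocity = 36,
                             lubricant = list(name = "BSF",
                                              viscosity = 3.5),
                             group = c("healthy-saline", "healthy-BSF",
                                       "degraded-saline", "degraded-BSF"),
                             applied_stress = 0.78) {
  group <- match.arg(group)
  n <- length(time)
  stopifnot(n >= 2, length(axial_force) == n, length(axial_disp) == n,
            length(torque) == n, plug_radius > 0,
            length(pair_thicknesses) == 2, all(pair_thicknesses > 0),
            angular_velocity > 0, lubricant$viscosity > 0,
            applied_stress > 0)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("record must be uniformly sampled")
  structure(list(time = time, axial_force = axial_force,
                 axial_disp = axial_disp, torque = torque,
                 plug_radius = plug_radius,
                 pair_thicknesses = pair_thicknesses,
                 angular_velocity = angular_velocity,
                 lubricant = lubricant, group = group,
                 applied_stress = applied_stress,
                 rate_hz = 1 / dt[1]),
            class = "tribology_record")
}

#' @export
print.tribology_record <- function(x, ...) {
  cat(sprintf(paste0("Tribology record: %s, %g deg/s, %s ",
                     "(%g mPa s), %d samples @ %g Hz\n"),
              x$group, x$angular_velocity, x$lubricant$name,
              x$lubricant$viscosity, length(x$time), x$rate_hz))
  invisible(x)
}

#' Write / read a tribology record (CSV + metadata sidecar JSON)
#'
#' @param record A [tribology_record()].
#' @param path CSV path; metadata goes to the same path with extension
#'   `.json`.
#' @return `read_tribology_record` returns the record; the writer
#'   returns `path` invisibly.
#' @export
write_tribology_record <- function(record, path) {
  stopifnot(inherits(record, "tribology_record"))
  utils::write.csv(data.frame(time_s = record$time,
                              axial_force_N = record$axial_force,
                              axial_disp_mm = record$axial_disp,
                              torque_Nm = record$torque),
                   path, row.names = FALSE)
  meta <- record[c("plug_radius", "pair_thicknesses", "angular_velocity",
                   "lubricant", "group", "applied_stress")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tribology_record
#' @export
read_tribology_record <- function(path) {
  d <- utils::read.csv(path)
  m <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                           simplifyVector = TRUE)
  tribology_record(d$time_s, d$axial_force_N, d$axial_disp_mm,
                   d$torque_Nm, plug_radius = m$plug_radius,
                   pair_thicknesses = m$pair_thicknesses,
                   angular_velocity = m$angular_velocity,
                   lubricant = as.list(m$lubricant), group = m$group,
                   applied_stress = m$applied_stress)
}

#' Lift-off detection and torque filtering
#'
#' Identifies the ten-second lift-off events from the axial force signal
#' (force below a fraction of the nominal load for at least
#' `min_duration`, extended by a guard band), excises them, and smooths
#' the stitched torque signal with a centred moving average.
#'
#' @param record A [tribology_record()].
#' @param threshold_frac Lift-off threshold as a fraction of the nominal
#'   load (default 0.2).
#' @param min_duration Minimum below-threshold duration \[s\] to count
#'   as a lift-off (default 5).
#' @param guard Guard margin added on both sides of each event \[s\]
#'   (default 2).
#' @param window_s Moving-average window \[s\] (default 10).
#' @return List with `torque_filtered` (NA inside exclusions), `keep`
#'   (logical), and `excluded_intervals` (two-column matrix of start/end
#'   times \[s\]).
#' @export
preprocess_signals <- function(record, threshold_frac = 0.2,
                               min_duration = 5, guard = 2,
                               window_s = 10) {
  stopifnot(inherits(record, "tribology_record"))
  rate <- record$rate_hz
  nominal <- record$applied_stress * 1e6 *
    pi * (record$plug_radius * 1e-3)^2
  low <- record$axial_force < threshold_frac * nominal
  n <- length(low)
  # contiguous below-threshold runs
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- rep(TRUE, n)
  intervals <- NULL
  gn <- round(guard * rate)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (r$lengths[i] < min_duration * rate) next
    a <- max(1, starts[i] - gn)
    b <- min(n, ends[i] + gn)
    keep[a:b] <- FALSE
    intervals <- rbind(intervals, c(record$time[a], record$time[b]))
  }
  if (mean(!keep) > 0.5)
    stop("record rejected: more than half of the samples fall in ",
         "lift-off exclusions")
  # moving average over the stitched (exclusion-removed) torque signal
  w <- max(1L, round(window_s * rate))
  if (w %% 2 == 0) w <- w + 1L
  tq <- record$torque[keep]
  sm <- stats::filter(tq, rep(1 / w, w), sides = 2)
  # shrink the window near the ends instead of returning NA
  half <- (w - 1L) / 2L
  m <- length(tq)
  if (m > 0) {
    cs <- cumsum(tq)
    for (i in which(is.na(sm))) {
      a <- max(1L, i - half); b <- min(m, i + half)
      sm[i] <- (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1)
    }
  }
  torque_filtered <- rep(NA_real_, n)
  torque_filtered[keep] <- as.numeric(sm)
  list(torque_filtered = torque_filtered, keep = keep,
       excluded_intervals = intervals)
}

#' Coefficient of friction for annular rotational contact
#'
#' `mu = (3/2) |torque| / (N r)`.
#'
#' @param torque Torque \[N m\].
#' @param load Axial load N \[N\], positive.
#' @param radius Plug radius \[m\].
#' @return Coefficient of friction (vectorised).
#' @export
compute_cof <- function(torque, load, radius) {
  if (any(load <= 0, na.rm = TRUE))
    stop("non-positive load outside excluded intervals: ",
         "lift-off detection failed")
  stopifnot(radius > 0)
  1.5 * abs(torque) / (load * radius)
}

#' Effective sliding velocity and Hersey number
#'
#' The effective radius of a rotating circular contact is
#' `r_eff = (2/3) r` (area-averaged tangential speed), so
#' `v_eff = omega * r_eff`. The Hersey number is velocity times lubricant
#' viscosity divided by load per unit length; the default convention
#' takes the load per unit length as `W / (2 r_eff)` (this is the
#' convention that reproduces the printed values for bovine synovial
#' fluid; `"2r"` and `"pi2r"` are selectable alternatives).
#'
#' @param omega Angular velocity \[deg/s\].
#' @param radius Plug radius \[mm\].
#' @param viscosity Lubricant viscosity \[mPa s\].
#' @param applied_stress Nominal stress \[MPa\].
#' @param convention Load-per-unit-length convention: `"2reff"`
#'   (default), `"2r"`, or `"pi2r"`.
#' @return List with `v_eff` \[mm/s\], `hersey` (dimensionless), and the
#'   intermediate `load_N` and `load_per_length_N_per_m`.
#' @export
#' @examples
#' kinematics(36, 3.5, 3.5, 0.78)$v_eff     # 1.5 mm/s
#' kinematics(1080, 3.5, 3.5, 0.78)$hersey  # 2.4e-8
kinematics <- function(omega, radius, viscosity, applied_stress,
                       convention = c("2reff", "2r", "pi2r")) {
  stopifnot(all(omega > 0), radius > 0, viscosity > 0, applied_stress > 0)
  convention <- match.arg(convention)
  r_m <- radius * 1e-3
  r_eff <- (2 / 3) * r_m
  v_eff <- omega * pi / 180 * r_eff            # m/s
  W <- applied_stress * 1e6 * pi * r_m^2       # N
  L_w <- switch(convention,
                "2reff" = W / (2 * r_eff),
                "2r" = W / (2 * r_m),
                "pi2r" = W / (pi * 2 * r_m))
  H <- v_eff * viscosity * 1e-3 / L_w
  list(v_eff = v_eff * 1e3, hersey = H, load_N = W,
       load_per_length_N_per_m = L_w)
}

#' Interpolate IFLS and strain from a creep solution onto a time grid
#'
#' @param solution A `creep_solution` from [run_creep()].
#' @param times Requested times \[s\] (must lie within the solution
#'   span).
#' @param applied_stress Nominal contact stress \[MPa\]; defaults to the
#'   solution's protocol value.
#' @return Data frame with `time`, `IFLS` (clipped to \[0, 1\]) and
#'   `strain`.
#' @export
compute_ifls_series <- function(solution, times, applied_stress = NULL) {
  stopifnot(inherits(solution, "creep_solution"))
  if (is.null(applied_stress))
    applied_stress <- attr(solution, "protocol")$applied_stress
  stp <- attr(solution, "steps")
  if (min(times) < 0 || max(times) > max(stp$time) + 1e-9)
    stop("requested times outside the simulated span; refusing to ",
         "extrapolate")
  por <- stats::approx(stp$time, stp$POR, times, rule = 2)$y
  disp <- stats::approx(stp$time, stp$displacement, times, rule = 2)$y
  data.frame(time = times,
             IFLS = pmin(pmax(por / applied_stress, 0), 1),
             strain = disp / attr(solution, "geometry")$thickness)
}

#' Ordinary least-squares line with standard errors
#'
#' Thin wrapper around `stats::lm` returning the slope/intercept, their
#' standard errors, and R^2 (defined as 0 when `y` is constant).
#'
#' @param x,y Numeric vectors.
#' @param context Label, e.g. `"mu_vs_ifls"` or `"eps_vs_ifls"`.
#' @return A `regression_result` list with `slope`, `intercept`,
#'   `r_squared`, `slope_sd`, `intercept_sd`, `n_points`, `context`.
#' @export
linear_regression <- function(x, y, context = "mu_vs_ifls") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate design: x is constant")
  if (stats::var(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          slope_sd = 0, intercept_sd = 0,
                          n_points = length(x), context = context),
                     class = "regression_result"))
  }
  f <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(f))  # exact fits are legitimate here
  structure(list(slope = unname(coef(f)[2]),
                 intercept = unname(coef(f)[1]),
                 r_squared = sm$r.squared,
                 slope_sd = sm$coefficients[2, 2],
                 intercept_sd = sm$coefficients[1, 2],
                 n_points = length(x), context = context),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s: y = %.4g x + %.4g (R^2 = %.4f, n = %d)\n",
              x$context, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Friction versus fluid load support analysis for one record
#'
#' Processes the raw signals ([preprocess_signals()]), computes the
#' coefficient-of-friction series, pairs each retained sample with the
#' model IFLS and strain at the same instant (both clocks zeroed at load
#' onset), and fits the linear law `mu = mu_IFLS * IFLS + mu_0` plus the
#' companion `mu` vs strain regression.
#'
#' @param record A [tribology_record()].
#' @param solution The fitted `creep_solution` for this pair.
#' @param liftoff_opts List of overrides for [preprocess_signals()].
#' @return List with `mu_ifls` and `mu_eps` ([linear_regression()]
#'   results), the paired table `pairs` (time, mu, IFLS, strain), the
#'   exclusion intervals, and `low_n` flag (fewer than 100 retained
#'   pairs).
#' @export
mu_ifls_analysis <- function(record, solution, liftoff_opts = list()) {
  stopifnot(inherits(record, "tribology_record"))
  pre <- do.call(preprocess_signals, c(list(record), liftoff_opts))
  keep <- pre$keep
  mu <- compute_cof(pre$torque_filtered[keep],
                    record$axial_force[keep],
                    record$plug_radius * 1e-3)
  mi <- compute_ifls_series(solution, record$time[keep])
  pairs <- data.frame(time = record$time[keep], mu = mu,
                      IFLS = mi$IFLS, strain = mi$strain)
  low_n <- nrow(pairs) < 100
  if (low_n) warning("fewer than 100 retained samples; ",
                     "regression flagged low-n")
  list(mu_ifls = linear_regression(pairs$IFLS, pairs$mu, "mu_vs_ifls"),
       mu_eps = linear_regression(pairs$strain, pairs$mu, "mu_vs_eps"),
       pairs = pairs, excluded_intervals = pre$excluded_intervals,
       low_n = low_n)
}

#' Assemble a Stribeck surface from per-velocity regressions
#'
#' Evaluates each velocity's `mu = mu_IFLS * IFLS + mu_0` regression on
#' an IFLS grid and interpolates linearly across log10 Hersey number.
#'
#' @param regressions List of `regression_result` (context
#'   `mu_vs_ifls`), one per velocity.
#' @param hersey Hersey number per regression.
#' @param ifls_grid IFLS evaluation grid.
#' @return A `stribeck_surface`: `ifls` (grid), `log10_hersey` (sorted
#'   knots), matrix `mu` (rows = IFLS, cols = knots), and an `eval(ifls,
#'   hersey)` interpolator.
#' @export
build_stribeck_surface <- function(regressions, hersey,
                                   ifls_grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(regressions) == length(hersey),
            length(regressions) >= 2)
  lh <- log10(hersey)
  if (anyDuplicated(signif(lh, 12))) {
    warning("duplicate Hersey values collapsed by averaging")
    sp <- split(seq_along(lh), signif(lh, 12))
    regressions <- lapply(sp, function(ix) {
      rs <- regressions[ix]
      structure(list(slope = mean(vapply(rs, `[[`, 0, "slope")),
                     intercept = mean(vapply(rs, `[[`, 0, "intercept")),
                     r_squared = NA, slope_sd = NA, intercept_sd = NA,
                     n_points = sum(vapply(rs, `[[`, 0L, "n_points")),
                     context = "mu_vs_ifls"),
                class = "regression_result")
    })
    lh <- as.numeric(names(sp))
  }
  o <- order(lh)
  lh <- lh[o]; regressions <- regressions[o]
  mu <- vapply(regressions,
               function(r) r$slope * ifls_grid + r$intercept,
               numeric(length(ifls_grid)))
  evalf <- function(ifls, hersey_val) {
    lx <- log10(hersey_val)
    if (lx <= lh[1]) j <- c(1, 1)
    else if (lx >= lh[length(lh)]) j <- rep(length(lh), 2)
    else {
      j2 <- findInterval(lx, lh) + 1
      j <- c(j2 - 1, j2)
    }
    w <- if (j[1] == j[2]) 0.5 else (lx - lh[j[1]]) / (lh[j[2]] - lh[j[1]])
    m1 <- regressions[[j[1]]]$slope * ifls + regressions[[j[1]]]$intercept
    m2 <- regressions[[j[2]]]$slope * ifls + regressions[[j[2]]]$intercept
    (1 - w) * m1 + w * m2
  }
  structure(list(ifls = ifls_grid, log10_hersey = lh, mu = mu,
                 regressions = regressions, eval = evalf),
            class = "stribeck_surface")
}

#' @export
print.stribeck_surface <- function(x, ...) {
  cat(sprintf("Stribeck surface: %d IFLS points x %d Hersey knots\n",
              length(x$ifls), length(x$log10_hersey)))
  invisible(x)
}

#' Nonparametric group statistics for per-sample outcomes
#'
#' Applies the study's statistics chain to a table of per-sample
#' outcomes: Kolmogorov-Smirnov normality screen per outcome,
#' Kruskal-Wallis across groups, Friedman test for the velocity effect
#' (samples as blocks), and Pearson correlations of the nonfibrillar
#' modulus with `mu_0` and `mu_IFLS`. The slowest articulation velocity
#' can be excluded from group comparisons.
#'
#' @param outcomes Data frame with columns `sample`, `group`,
#'   `velocity`, and one column per outcome named in `outcome_cols`.
#' @param outcome_cols Character vector of outcome column names.
#' @param exclude_slowest Exclude the slowest velocity from the
#'   Kruskal-Wallis group comparisons (default TRUE).
#' @param e_nf Optional named vector (by sample) of fitted `E_nf` for
#'   the Pearson correlations.
#' @return A `stats_report` list: `normality` (KS p per outcome),
#'   `kruskal` (per outcome: statistic, p, n per group), `friedman`
#'   (per outcome), `pearson` (if `e_nf` given), `excluded_conditions`.
#' @export
group_stats <- function(outcomes, outcome_cols,
                        exclude_slowest = TRUE, e_nf = NULL) {
  stopifnot(all(c("sample", "group", "velocity") %in% names(outcomes)),
            all(outcome_cols %in% names(outcomes)))
  excluded <- character(0)
  kw_data <- outcomes
  if (exclude_slowest) {
    vmin <- min(outcomes$velocity)
    kw_data <- outcomes[outcomes$velocity > vmin, ]
    excluded <- sprintf("velocity=%g excluded from group comparisons",
                        vmin)
  }
  normality <- lapply(outcome_cols, function(oc) {
    x <- outcomes[[oc]]
    x <- x[is.finite(x)]
    suppressWarnings(
      stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
  })
  names(normality) <- outcome_cols

  kruskal <- lapply(outcome_cols, function(oc) {
    d <- kw_data[is.finite(kw_data[[oc]]), ]
    ng <- table(d$group)
    if (any(ng < 2) || length(ng) < 2)
      return(list(statistic = NA, p_value = NA, n = as.list(ng),
                  skipped = TRUE))
    kt <- stats::kruskal.test(d[[oc]], factor(d$group))
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         n = as.list(ng), skipped = FALSE)
  })
  names(kruskal) <- outcome_cols

  friedman <- lapply(outcome_cols, function(oc) {
    d <- outcomes[is.finite(outcomes[[oc]]), ]
    tab <- table(d$sample, d$velocity)
    if (any(tab != 1))
      return(list(statistic = NA, p_value = NA, skipped = TRUE))
    ft <- stats::friedman.test(d[[oc]], factor(d$velocity),
                               factor(d$sample))
    st <- unname(ft$statistic)
    # fully tied blocks (no variation to rank) mean no velocity effect
    if (is.nan(st)) return(list(statistic = 0, p_value = 1,
                                skipped = FALSE))
    list(statistic = st, p_value = ft$p.value, skipped = FALSE)
  })
  names(friedman) <- outcome_cols

  pearson <- NULL
  if (!is.null(e_nf)) {
    pearson <- lapply(intersect(c("mu_0", "mu_IFLS"), outcome_cols),
                      function(oc) {
      agg <- stats::aggregate(outcomes[[oc]],
                              list(sample = outcomes$sample), mean)
      x <- e_nf[as.character(agg$sample)]
      ok <- is.finite(x) & is.finite(agg$x)
      if (sum(ok) < 3) return(list(r = NA, r_squared = NA, p_value = NA))
      ct <- stats::cor.test(x[ok], agg$x[ok])
      list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
           p_value = ct$p.value)
    })
    names(pearson) <- intersect(c("mu_0", "mu_IFLS"), outcome_cols)
  }
  structure(list(normality = normality, kruskal = kruskal,
                 friedman = friedman, pearson = pearson,
                 excluded_conditions = excluded),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Group statistics report\n")
  for (oc in names(x$kruskal)) {
    k <- x$kruskal[[oc]]
    cat(sprintf("  %s: KS-normality p = %.3g; Kruskal-Wallis p = %.3g\n",
                oc, x$normality[[oc]], k$p_value))
  }
  if (length(x$excluded_conditions))
    cat("  exclusions:", x$excluded_conditions, "\n")
  invisible(x)
}
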