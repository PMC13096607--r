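# short protocol keeping ramp + three decades of hold for fast records
short_protocol <- function(hold = 600) {
  loading_protocol(0.78, 0.5, hold)
}

test_that("group parameter draws are reproducible, respect dispersion,
          and encode the degraded contrast", {
  specs <- default_group_specs()
  a <- sample_group_params(specs[["healthy-saline"]], 5, seed = 42)
  b <- sample_group_params(specs[["healthy-saline"]], 5, seed = 42)
  expect_identical(a, b)
  # zero dispersion collapses onto the medians
  s0 <- group_spec("healthy-saline",
                   specs[["healthy-saline"]]$median_params,
                   dispersion = 0)
  d0 <- sample_group_params(s0, 3, seed = 1)
  for (p in d0$params) expect_equal(p$E_nf, 0.3)
  # large-n medians: degraded E_nf about a third of healthy, k0 higher
  dh <- sample_group_params(specs[["healthy-saline"]], 1000, seed = 2)
  dd <- sample_group_params(specs[["degraded-saline"]], 1000, seed = 3)
  mh <- median(vapply(dh$params, `[[`, 0, "E_nf"))
  md <- median(vapply(dd$params, `[[`, 0, "E_nf"))
  expect_equal(md, mh / 3, tolerance = 0.1)
  expect_gt(median(vapply(dd$params, `[[`, 0, "k0")),
            2 * median(vapply(dh$params, `[[`, 0, "k0")))
})

test_that("noise-free records invert exactly through the friction
          formula and pass pipeline validation", {
  specs <- default_group_specs()
  sp <- specs[["healthy-saline"]]
  sp$noise <- list(disp_um = 0, torque_Nm = 0, force_N = 0)
  syn <- synthesize_record(healthy_params(), c(1.7, 1.7), sp, 36,
                           protocol = short_protocol(),
                           seed = 5, liftoffs = FALSE)
  rec <- syn$record
  mu_rec <- compute_cof(rec$torque, rec$axial_force,
                        rec$plug_radius * 1e-3)
  expect_equal(mu_rec, syn$truth$mu_true, tolerance = 1e-12)
  # within the linear regime the generating law itself is recovered
  lin <- !syn$truth$clamped
  expect_equal(mu_rec[lin], (-0.15 * syn$truth$ifls + 0.11)[lin],
               tolerance = 1e-12)
  # record passes the pipeline input validation and preprocessing
  pre <- preprocess_signals(rec)
  expect_true(all(pre$keep))
  # displacement is twice the modelled layer displacement
  sol <- syn$truth$solution
  expect_equal(rec$axial_disp[length(rec$axial_disp)],
               2 * max(attr(sol, "steps")$displacement),
               tolerance = 1e-6)
})

test_that("lift-off blocks appear on schedule and are excluded by the
          pipeline", {
  specs <- default_group_specs()
  syn <- synthesize_record(healthy_params(), c(1.7, 1.7),
                           specs[["healthy-saline"]], 1080,
                           protocol = short_protocol(),
                           seed = 6, liftoffs = TRUE)
  pre <- preprocess_signals(syn$record)
  expect_gt(nrow(pre$excluded_intervals), 1)
  expect_equal(sum(syn$truth$lifted & pre$keep), 0)
})

test_that("friction-law recovery degrades gracefully from noiseless to
          noisy records", {
  specs <- default_group_specs()
  sp <- specs[["healthy-saline"]]
  errs <- c()
  for (noise in c(0, 2e-4, 1e-3)) {
    sp$noise <- list(disp_um = 0, torque_Nm = noise, force_N = 0)
    syn <- synthesize_record(healthy_params(), c(1.7, 1.7), sp, 36,
                             protocol = short_protocol(2000),
                             seed = 7, liftoffs = FALSE)
    an <- mu_ifls_analysis(syn$record, syn$truth$solution)
    # regression restricted to the linear regime of the generating law
    lin <- !syn$truth$clamped
    fit <- linear_regression(an$pairs$IFLS[lin], an$pairs$mu[lin])
    errs <- c(errs, abs(fit$slope + 0.15))
    if (noise == 0)
      expect_lt(abs(fit$slope + 0.15), 2e-3)
  }
  expect_true(all(diff(errs) >= -1e-4))
})

test_that("degraded generating law is more nonlinear than the healthy
          one, as seen by the linear-fit R^2", {
  specs <- default_group_specs()
  quiet <- list(disp_um = 0, torque_Nm = 0, force_N = 0)
  sph <- specs[["healthy-saline"]]; sph$noise <- quiet
  spd <- specs[["degraded-saline"]]; spd$noise <- quiet
  sh <- synthesize_record(healthy_params(), c(1.7, 1.7), sph, 36,
                          protocol = short_protocol(2000), seed = 8,
                          liftoffs = FALSE)
  pd <- material_params(E_nf = 0.1, E_f0 = 0.67, E_feps = 33,
                        k0 = 6e-15, M = 5)
  sd_ <- synthesize_record(pd, c(2.1, 2.1), spd, 36,
                           protocol = short_protocol(2000), seed = 9,
                           liftoffs = FALSE)
  rh <- mu_ifls_analysis(sh$record, sh$truth$solution)
  rd <- mu_ifls_analysis(sd_$record, sd_$truth$solution)
  linh <- !sh$truth$clamped; lind <- !sd_$truth$clamped
  r2h <- linear_regression(rh$pairs$IFLS[linh],
                           rh$pairs$mu[linh])$r_squared
  r2d <- linear_regression(rd$pairs$IFLS[lind],
                           rd$pairs$mu[lind])$r_squared
  expect_gt(r2h, r2d)
})

test_that("fixture set writes the full study layout with reproducible
          ground truth", {
  out1 <- file.path(tempdir(), "fix1")
  out2 <- file.path(tempdir(), "fix2")
  man1 <- write_fixture_set(out1, seed = 3, protocol = short_protocol(60),
                            liftoffs = FALSE)
  man2 <- write_fixture_set(out2, seed = 3, protocol = short_protocol(60),
                            liftoffs = FALSE)
  expect_length(man1$records, 4 * 3 * 4)   # groups x pairs x velocities
  expect_length(list.files(out1, pattern = "\\.csv$"), 48)
  expect_identical(man1, man2)
  expect_identical(unname(tools::md5sum(file.path(out1, man1$records[[1]]$file))),
                   unname(tools::md5sum(file.path(out2, man2$records[[1]]$file))))
  # manifest ground truth round-trips through the JSON reader
  m <- jsonlite::read_json(file.path(out1, "manifest.json"),
                           simplifyVector = FALSE)
  r1 <- m$records[[1]]
  expect_equal(r1$truth_params$E_nf, man1$records[[1]]$truth_params$E_nf)
  rec <- read_tribology_record(file.path(out1, r1$file))
  expect_s3_class(rec, "tribology_record")
  unlink(c(out1, out2), recursive = TRUE)
})
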