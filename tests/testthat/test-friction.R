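# helper: a clean record with constant force/torque at 10 Hz
flat_record <- function(duration = 300, force = NULL, torque = 0.007,
                        omega = 36, group = "healthy-saline") {
  t <- seq(0.1, duration, by = 0.1)
  W <- 0.78e6 * pi * 0.0035^2
  if (is.null(force)) force <- rep(W, length(t))
  tribology_record(t, force, rep(0.3, length(t)),
                   rep(torque, length(t)), angular_velocity = omega,
                   lubricant = list(name = "saline", viscosity = 0.9),
                   group = group)
}

test_that("lift-off dips are detected as single excluded intervals and
          the remainder is retained", {
  rec <- flat_record(600)
  # two 10-s dips to near zero
  dip <- function(t0) rec$time > t0 & rec$time <= t0 + 10
  rec$axial_force[dip(100) | dip(400)] <- 0.5
  pre <- preprocess_signals(rec)
  expect_equal(nrow(pre$excluded_intervals), 2)
  expect_true(all(!pre$keep[dip(100)]))
  expect_true(all(!pre$keep[dip(400)]))
  # guard band of 2 s on both sides
  expect_equal(sum(!pre$keep), 2 * (10 + 4) * 10, tolerance = 0.05)
  # bookkeeping: retained + excluded = total, no overlap
  expect_equal(sum(pre$keep) + sum(!pre$keep), length(rec$time))
})

test_that("rejects records that are mostly lift-off", {
  rec <- flat_record(100)
  rec$axial_force[rec$time > 10] <- 0.1
  expect_error(preprocess_signals(rec), "rejected")
})

test_that("moving average preserves constants and attenuates single
          spikes by the window factor", {
  rec <- flat_record(300)
  pre <- preprocess_signals(rec)
  expect_equal(pre$torque_filtered, rep(0.007, length(rec$time)),
               tolerance = 1e-12)
  spike <- 0.05
  rec2 <- flat_record(300)
  rec2$torque[1500] <- rec2$torque[1500] + spike
  pre2 <- preprocess_signals(rec2)
  dev <- abs(pre2$torque_filtered - 0.007)
  expect_lt(max(dev, na.rm = TRUE), spike / (10 * 10) + 1e-12)
})

test_that("coefficient of friction formula matches the printed
          arithmetic and is linear in torque", {
  expect_equal(compute_cof(0, 30, 0.0035), 0)
  expect_equal(compute_cof(0.007, 30, 0.0035), 0.1)
  expect_equal(compute_cof(0.014, 30, 0.0035),
               2 * compute_cof(0.007, 30, 0.0035))
  expect_error(compute_cof(0.007, -1, 0.0035), "lift-off")
})

test_that("effective velocities and Hersey numbers reproduce the
          printed values", {
  ks <- lapply(c(36, 108, 360, 1080),
               function(w) kinematics(w, 3.5, 3.5, 0.78))
  expect_equal(sapply(ks, `[[`, "v_eff"), c(1.5, 4.4, 15, 44),
               tolerance = 0.02)
  expect_equal(sapply(ks, `[[`, "hersey"),
               c(8.1e-10, 2.4e-9, 8.1e-9, 2.4e-8), tolerance = 0.02)
  # saline spans a different Hersey range at the same velocities
  expect_equal(kinematics(36, 3.5, 0.9, 0.78)$hersey,
               8.1e-10 * 0.9 / 3.5, tolerance = 0.02)
  expect_error(kinematics(36, 3.5, 3.5, 0.78, convention = "bogus"))
})

test_that("unit invariance: converting the inputs and converting back
          leaves mu unchanged", {
  mu1 <- compute_cof(0.007, 30, 0.0035)
  # torque in N mm and radius in mm: same dimensionless result
  mu2 <- compute_cof(0.007 * 1e3, 30, 3.5)
  expect_equal(mu1, mu2)
})

test_that("ordinary least squares recovers exact lines, handles
          constant y, and has calibrated coverage", {
  x <- seq(0, 1, length.out = 50)
  r <- linear_regression(x, -0.15 * x + 0.11)
  expect_equal(r$slope, -0.15)
  expect_equal(r$intercept, 0.11)
  expect_equal(r$r_squared, 1)
  rc <- linear_regression(x, rep(0.06, 50))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_error(linear_regression(rep(1, 10), rnorm(10)), "degenerate")
  # Monte-Carlo: slope within 2 SE of truth in about 95% of replicates
  set.seed(11)
  hits <- replicate(500, {
    y <- -0.15 * x + 0.11 + rnorm(50, 0, 0.01)
    f <- linear_regression(x, y)
    abs(f$slope + 0.15) < 2 * f$slope_sd
  })
  expect_gt(mean(hits), 0.925)
})

test_that("Stribeck surface reproduces source regressions at the knots
          and inherits negative IFLS slopes", {
  regs <- list(linear_regression(c(0, 0.5, 1), c(0.11, 0.035, -0.04)),
               linear_regression(c(0, 0.5, 1), c(0.06, 0.025, -0.01)))
  H <- c(8.1e-10, 2.4e-9)
  surf <- build_stribeck_surface(regs, H)
  for (ifls in c(0, 0.3, 0.8))
    expect_equal(surf$eval(ifls, H[1]),
                 regs[[1]]$slope * ifls + regs[[1]]$intercept)
  # negative slope everywhere in between
  mid <- sqrt(prod(H))
  expect_lt(surf$eval(0.9, mid), surf$eval(0.1, mid))
  # identical inputs give a Hersey-independent surface
  surf2 <- build_stribeck_surface(regs[c(1, 1)], H)
  expect_equal(surf2$eval(0.4, H[1]), surf2$eval(0.4, H[2]))
})

test_that("group statistics: perfect correlation, zero Friedman under
          identical blocks, and slowest-velocity exclusion", {
  set.seed(3)
  out <- expand.grid(sample = paste0("s", 1:6),
                     velocity = c(1.5, 4.4, 15, 44))
  out$group <- rep(c("healthy-saline", "degraded-saline"), each = 3)
  out$mu_0 <- rep(seq(0.04, 0.11, length.out = 6), 4)
  out$mu_IFLS <- -out$mu_0
  e_nf <- setNames(seq(0.1, 0.35, length.out = 6), paste0("s", 1:6))
  rep_ <- group_stats(out, c("mu_0", "mu_IFLS"), e_nf = e_nf)
  expect_equal(rep_$pearson$mu_0$r, 1, tolerance = 1e-12)
  expect_equal(rep_$friedman$mu_0$statistic, 0)
  expect_match(rep_$excluded_conditions, "velocity=1.5")
  # with exclusion off, all velocities enter the KW comparison
  rep2 <- group_stats(out, "mu_0", exclude_slowest = FALSE)
  expect_length(rep2$excluded_conditions, 0)
})

test_that("Kruskal-Wallis type-I error is calibrated at the 5% level",
{
  set.seed(123)
  rejections <- replicate(1000, {
    g <- rep(c("a", "b"), each = 20)
    x <- rnorm(40)
    stats::kruskal.test(x, factor(g))$p.value < 0.05
  })
  expect_equal(mean(rejections), 0.05, tolerance = 0.3)
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("records round-trip through CSV + sidecar JSON", {
  rec <- flat_record(60)
  f <- file.path(tempdir(), "rec_roundtrip.csv")
  write_tribology_record(rec, f)
  rec2 <- read_tribology_record(f)
  for (nm in c("time", "axial_force", "axial_disp", "torque"))
    expect_equal(rec2[[nm]], rec[[nm]])
  expect_equal(rec2$group, rec$group)
  expect_equal(rec2$lubricant$viscosity, rec$lubricant$viscosity)
})
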