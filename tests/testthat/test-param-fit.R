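# small, fast fitting problems (tiny mesh, short hold) exercise the
# optimiser plumbing; accuracy at study scale is covered in the
# acceptance tests
tiny_geo <- function() creep_geometry(thickness = 1.7, n_r = 8, n_z = 6)

tiny_problem <- function(noise_sd = 0, n_starts = 4, seed = 99) {
  truth <- healthy_params()
  tt <- sort(unique(c(seq(0.1, 0.5, by = 0.1),
                      10^seq(log10(0.6), log10(600), length.out = 25))))
  prot <- loading_protocol(0.78, 0.5, 600, output_times = tt)
  sol <- run_creep(truth, tiny_geo(), prot, fit_solver_options())
  set.seed(seed)
  target <- 2 * sol$displacement + rnorm(length(tt), 0, noise_sd)
  fit_problem(tt, target, tiny_geo(), prot, n_starts = n_starts)
}

test_that("reported RMSE equals the independently recomputed RMSE of
          the stored best fit", {
  prob <- tiny_problem()
  fr <- fit_parameters(prob, fit_solver_options(), max_eval = 60,
                       n_refine = 1, rmse_tol = 1e-7)
  again <- sqrt(mean((fr$best_curve$model - fr$best_curve$target)^2))
  expect_equal(fr$rmse, again, tolerance = 1e-12)
  expect_true(fr$converged)
  expect_equal(nrow(fr$per_start), 4)
})

test_that("the objective is invariant to the time unit of the input
          after normalisation", {
  prob_s <- tiny_problem()
  prob_ms <- fit_problem(prob_s$target_time * 1e3,
                         prob_s$target_displacement,
                         prob_s$geometry, prob_s$protocol,
                         n_starts = 4, time_unit = "ms")
  th <- list(E_nf = 0.25, E_f0 = 1.5, E_feps = 80, k0 = 3e-15, M = 4)
  expect_equal(cartifls:::fit_cost(th, prob_s, fit_solver_options()),
               cartifls:::fit_cost(th, prob_ms, fit_solver_options()))
})

test_that("short target series trigger the identifiability warning", {
  tt <- seq(1, 20, by = 1)
  expect_warning(fit_problem(tt, tt * 0.01,
                             protocol = loading_protocol(0.78, 0.5, 30)),
                 "decades")
})

test_that("parameter recovery error grows monotonically with the
          displacement noise level", {
  errs <- vapply(c(0, 0.02, 0.1), function(sd_mm) {
    prob <- tiny_problem(noise_sd = sd_mm, seed = 7)
    fr <- fit_parameters(prob, fit_solver_options(), max_eval = 220,
                         n_refine = 1, rmse_tol = 1e-7)
    abs(fr$params$E_nf / 0.3 - 1)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-6))
})

test_that("starts that converge to the solution basin agree on the
          parameters (multi-start restart verification)", {
  prob <- tiny_problem(noise_sd = 2e-3, n_starts = 8, seed = 7)
  fr <- fit_parameters(prob, fit_solver_options(), max_eval = 250,
                       n_refine = 4, rmse_tol = 0)
  ref <- fr$per_start[fr$per_start$refined & fr$per_start$converged, ]
  expect_gte(nrow(ref), 2)
  # the per-start table exposes local minima; every start that reaches
  # the solution basin (RMSE within 20% of the best, i.e. at the noise
  # floor) must report the same parameters -- starts caught in other
  # basins are visibly worse in the table
  basin <- ref[ref$rmse < 1.2 * fr$rmse, ]
  expect_gte(nrow(basin), 1)
  expect_true(all(abs(basin$E_nf / fr$params$E_nf - 1) < 0.1))
  expect_true(all(abs(basin$k0 / fr$params$k0 - 1) < 0.1))
  # refinement improves decisively on every screened start, and the
  # best fit sits near the generating parameters
  expect_lt(fr$rmse, 0.1 * min(fr$per_start$rmse[!fr$per_start$refined]))
  expect_lt(abs(fr$params$E_nf / 0.3 - 1), 0.15)
  expect_lt(abs(fr$params$k0 / 2e-15 - 1), 0.15)
})
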