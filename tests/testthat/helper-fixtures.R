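# Shared fixtures. Expensive simulations are computed lazily and cached
# for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

healthy_params <- function() {
  material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100, k0 = 2e-15, M = 5)
}

coarse_geometry <- function() creep_geometry(thickness = 1.7,
                                             n_r = 15, n_z = 10)

# default healthy creep on the coarse mesh, full 10,000 s protocol
healthy_run <- function() cached("healthy_run", {
  run_creep(healthy_params(), coarse_geometry(), loading_protocol())
})

fit_solver_options <- function() {
  # fast stepping for fitting loops; pathological parameter draws fail
  # fast (few halvings) instead of grinding through tiny steps
  solver_options(newton_tol = 1e-5, dt0 = 0.1, dt_growth = 2,
                 dt_max = 1000, max_halvings = 8, max_steps = 1000)
}
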