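#!/usr/bin/env Rscript
# Friction-IFLS analysis over the cohort: for every record, excise the
# lift-offs, smooth the torque, compute the coefficient of friction,
# pair it with the simulated IFLS and strain at the same instants, and
# fit mu = mu_IFLS * IFLS + mu_0 plus the strain-IFLS line. Produces
# the per-group x velocity regression table (Table-1 layout) and the
# strain-IFLS coefficients.
#
# IFLS here comes from each pair's ground-truth forward simulation (the
# fitted parameters of 02_fit_creep.R reproduce those curves to R^2 >
# 0.99; using the truth simulation keeps this driver fast).

library(cartifls)

raw <- "scratch/cohort"
manifest <- jsonlite::read_json(file.path(raw, "manifest.json"),
                                simplifyVector = FALSE)

rows <- list(); eps_rows <- list()
for (r in manifest$records) {
  rec <- read_tribology_record(file.path(raw, r$file))
  params <- material_params(E_nf = r$truth_params$E_nf,
                            E_f0 = r$truth_params$E_f0,
                            E_feps = r$truth_params$E_feps,
                            k0 = r$truth_params$k0, M = r$truth_params$M)
  sol <- run_creep(params,
                   creep_geometry(thickness = mean(unlist(r$thicknesses)),
                                  n_r = 15, n_z = 10),
                   loading_protocol(),
                   solver_options(newton_tol = 1e-5, dt0 = 0.1,
                                  dt_growth = 1.6, dt_max = 500))
  an <- mu_ifls_analysis(rec, sol)
  kin <- kinematics(rec$angular_velocity, rec$plug_radius,
                    rec$lubricant$viscosity, rec$applied_stress)
  rows[[r$file]] <- data.frame(
    group = r$group, pair = r$pair, v_eff = round(kin$v_eff, 1),
    hersey = kin$hersey, mu_IFLS = an$mu_ifls$slope,
    mu_IFLS_sd = an$mu_ifls$slope_sd, mu_0 = an$mu_ifls$intercept,
    mu_0_sd = an$mu_ifls$intercept_sd, r_squared = an$mu_ifls$r_squared,
    mu_ifls_true = r$truth_law$mu_ifls, mu_0_true = r$truth_law$mu_0)
  eref <- linear_regression(an$pairs$IFLS, an$pairs$strain,
                            context = "eps_vs_ifls")
  eps_rows[[r$file]] <- data.frame(
    group = r$group, pair = r$pair, v_eff = round(kin$v_eff, 1),
    slope = eref$slope, eps0 = eref$intercept,
    r_squared = eref$r_squared)
}
mu_tab <- do.call(rbind, rows)
eps_tab <- do.call(rbind, eps_rows)
write.csv(mu_tab, "results/mu_ifls_table.csv", row.names = FALSE)
write.csv(eps_tab, "results/eps_ifls_table.csv", row.names = FALSE)

agg <- aggregate(cbind(mu_IFLS, mu_0, r_squared) ~ group + v_eff,
                 mu_tab, mean)
message("Group-mean mu-IFLS regressions (compare to the generating laws):")
print(agg, digits = 3)
message("Strain at zero fluid load support, eps(0), by tissue state:")
print(aggregate(eps0 ~ group, eps_tab, mean), digits = 3)
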