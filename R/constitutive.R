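#' Material parameter set for the fibril-reinforced poroviscoelastic model
#'
#' Bundles the five specimen-specific constitutive parameters that are
#' identified from creep data together with the fixed model constants.
#' The solid skeleton is split into a tension-only viscoelastic collagen
#' fibril network (moduli `E_f0`, `E_feps`, damping `eta_fibril`) and an
#' isotropic Neo-Hookean nonfibrillar matrix (`E_nf`, `nu`); interstitial
#' fluid flow follows Darcy's law with deformation-dependent permeability
#' (`k0`, `M`).
#'
#' @param E_nf Nonfibrillar matrix Young's modulus \[MPa\].
#' @param E_f0 Initial (zero-strain) fibril network modulus \[MPa\].
#' @param E_feps Strain dependence of the fibril network modulus
#'   \[MPa per unit strain\]; the network tangent modulus at fibril strain
#'   `eps` is `E_f0 + E_feps * eps`.
#' @param k0 Initial hydraulic permeability \[m^4/(N s)\].
#' @param M Exponent of the deformation dependence of permeability
#'   (dimensionless); the current permeability is `k0 * J^M` where `J` is
#'   the local volume ratio.
#' @param nu Poisson's ratio of the nonfibrillar matrix (fixed 0.47 by
#'   default).
#' @param eta_fibril Damping coefficient of the viscoelastic fibrils
#'   \[MPa s\] (fixed 947 by default).
#' @param e0 Initial void ratio (fluid/solid volume; fixed 3.5 by default,
#'   equivalent to a water fraction of 78 percent).
#'
#' @return An object of class `material_params` (a validated named list).
#' @export
#' @examples
#' p <- material_params(E_nf = 0.3, E_f0 = 2, E_feps = 100,
#'                      k0 = 2e-15, M = 5)
#' porosity_from_void_ratio(p$e0)
material_params <- function(E_nf, E_f0, E_feps, k0, M,
                            nu = 0.47, eta_fibril = 947, e0 = 3.5) {
  stopifnot(is.numeric(E_nf), length(E_nf) == 1L, E_nf > 0,
            is.numeric(E_f0), E_f0 >= 0,
            is.numeric(E_feps), E_feps >= 0,
            is.numeric(k0), k0 > 0,
            is.numeric(M), M >= 0,
            is.numeric(nu), nu >= 0, nu < 0.5,
            is.numeric(eta_fibril), eta_fibril > 0,
            is.numeric(e0), e0 > 0)
  structure(list(E_nf = E_nf, E_f0 = E_f0, E_feps = E_feps,
                 k0 = k0, M = M, nu = nu,
                 eta_fibril = eta_fibril, e0 = e0),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Fibril-reinforced poroviscoelastic material parameters\n")
  cat(sprintf("  E_nf   = %g MPa (nonfibrillar matrix modulus)\n", x$E_nf))
  cat(sprintf("  E_f0   = %g MPa (initial fibril network modulus)\n", x$E_f0))
  cat(sprintf("  E_feps = %g MPa (strain dependence of fibril modulus)\n",
              x$E_feps))
  cat(sprintf("  k0     = %g m^4/(N s) (initial permeability)\n", x$k0))
  cat(sprintf("  M      = %g (permeability strain exponent)\n", x$M))
  cat(sprintf("  fixed: nu = %g, eta_fibril = %g MPa s, e0 = %g\n",
              x$nu, x$eta_fibril, x$e0))
  invisible(x)
}

#' Write / read material parameters as self-describing JSON
#'
#' @param params A [material_params()] object.
#' @param path File path.
#' @return `write_material_params` returns `path` invisibly;
#'   `read_material_params` returns a [material_params()] object.
#' @export
write_material_params <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  x <- list(E_nf_MPa = params$E_nf, E_f0_MPa = params$E_f0,
            E_feps_MPa = params$E_feps, k0_m4_per_Ns = params$k0,
            M = params$M, nu = params$nu,
            eta_fibril_MPa_s = params$eta_fibril, e0 = params$e0)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_params
#' @export
read_material_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  material_params(E_nf = x$E_nf_MPa, E_f0 = x$E_f0_MPa,
                  E_feps = x$E_feps_MPa, k0 = x$k0_m4_per_Ns, M = x$M,
                  nu = x$nu, eta_fibril = x$eta_fibril_MPa_s, e0 = x$e0)
}

#' Porosity (water fraction) from void ratio
#'
#' @param e Void ratio (fluid volume / solid volume).
#' @return Porosity `e / (1 + e)`.
#' @export
porosity_from_void_ratio <- function(e) {
  stopifnot(all(e > 0))
  e / (1 + e)
}

#' Neo-Hookean effective Cauchy stress of the nonfibrillar matrix
#'
#' Compressible Neo-Hookean law carrying all compressive stresses:
#' `sigma = (mu_s/J) (B - I) + (lambda_s/J) ln(J) I`, with `B = F F^T`,
#' `J = det F`, and Lame constants derived from (`E_nf`, `nu`).
#' Converges to isotropic linear elasticity as `F -> I`.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param E_nf Young's modulus \[MPa\].
#' @param nu Poisson's ratio.
#' @return Symmetric 3x3 Cauchy stress \[MPa\].
#' @export
neo_hookean_stress <- function(F, E_nf, nu) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("degenerate deformation: det(F) must be positive")
  mu_s <- E_nf / (2 * (1 + nu))
  lambda_s <- E_nf * nu / ((1 + nu) * (1 - 2 * nu))
  B <- F %*% t(F)
  (mu_s / J) * (B - diag(3)) + (lambda_s / J) * log(J) * diag(3)
}

#' Create the internal state of a single fibril (direction + history)
#'
#' @param direction Unit vector (length 3) giving the fibril direction in
#'   the axisymmetric (r, z, theta) frame.
#' @param eps_f Current fibril strain.
#' @param overstress_q Viscous overstress of the Maxwell branch \[MPa\].
#' @return A `fibril_state` list.
#' @export
fibril_state <- function(direction = c(1, 0, 0), eps_f = 0,
                         overstress_q = 0) {
  nrm <- sqrt(sum(direction^2))
  stopifnot(abs(nrm - 1) < 1e-8)
  if (eps_f <= 0 && overstress_q != 0)
    stop("overstress must be zero when the fibril is not in tension")
  structure(list(direction = direction, eps_f = eps_f,
                 overstress_q = overstress_q),
            class = "fibril_state")
}

#' One backward-Euler update of the tension-only viscoelastic fibril law
#'
#' The fibril carries stress only in tension. In tension the stress is the
#' sum of an equilibrium nonlinear spring,
#' `sigma_eq(eps) = E_f0 eps + 0.5 E_feps eps^2` (tangent modulus
#' `E_f0 + E_feps eps`), and the overstress `q` of a Maxwell branch with
#' the same strain-dependent tangent modulus and damping `eta_fibril`:
#' `dq/dt = E_tan(eps) deps/dt - (E_tan(eps)/eta) q`. The update
#' integrates this ODE exactly over the step (exponential map with the
#' tangent modulus frozen at the end-of-step strain and a constant
#' strain rate), which stays accurate when the step is not small against
#' the relaxation time `eta / E_tan`. At or below zero strain the stress
#' is zero and the overstress history is wiped.
#'
#' @param eps_f_new Fibril strain at the end of the step.
#' @param dt Time step \[s\], positive.
#' @param state A [fibril_state()] carrying the strain and overstress at
#'   the start of the step.
#' @param params A [material_params()] object.
#' @return List with `sigma_f` (fibril stress \[MPa\]) and `state`
#'   (updated [fibril_state()]).
#' @export
fibril_stress_update <- function(eps_f_new, dt, state, params) {
  stopifnot(dt > 0, inherits(state, "fibril_state"),
            inherits(params, "material_params"))
  if (eps_f_new <= 0) {
    new_state <- fibril_state(state$direction, eps_f_new, 0)
    return(list(sigma_f = 0, state = new_state))
  }
  E_tan <- params$E_f0 + params$E_feps * eps_f_new
  eta <- params$eta_fibril
  deps <- eps_f_new - max(state$eps_f, 0)
  x <- dt * E_tan / eta                  # dt over the relaxation time
  # exact integration over the step at constant strain rate; expm1
  # keeps the small-x limit (q += E_tan * deps) at full precision
  q_new <- state$overstress_q * exp(-x) -
    (eta * deps / dt) * expm1(-x)
  sigma_eq <- params$E_f0 * eps_f_new + 0.5 * params$E_feps * eps_f_new^2
  sigma_f <- sigma_eq + q_new
  if (sigma_f < 0) {
    # a tension-only fibril cannot push: during rapid unloading the
    # dashpot would otherwise drive the total below zero
    sigma_f <- 0
    q_new <- -sigma_eq
  }
  # smooth recruitment over a 1e-4 strain window (fibril uncrimping):
  # keeps the stress continuous when fibrils cross the tension gate
  # with residual overstress, which exact Newton needs
  eps_s <- 1e-4
  if (eps_f_new < eps_s) {
    s <- eps_f_new / eps_s
    sigma_f <- sigma_f * s * s * (3 - 2 * s)
  }
  new_state <- fibril_state(state$direction, eps_f_new, q_new)
  list(sigma_f = sigma_f, state = new_state)
}

#' Deformation-dependent permeability
#'
#' `k = k0 * ((1 + e) / (1 + e0))^M` with `1 + e = J (1 + e0)`, i.e.
#' `k = k0 * J^M`: compaction (J < 1) closes pores and reduces
#' permeability; the reference state (J = 1) returns `k0`.
#'
#' @param J Volume ratio `det(F)`, positive.
#' @param params A [material_params()] object (uses `k0`, `M`).
#' @return Permeability \[m^4/(N s)\].
#' @export
permeability <- function(J, params) {
  stopifnot(inherits(params, "material_params"))
  if (any(!is.finite(J)) || any(J <= 0))
    stop("degenerate deformation: volume ratio must be positive")
  params$k0 * J^params$M
}

#' Homogeneous fibril network layout for the axisymmetric model
#'
#' Primary fibrils run parallel to the articular surface (unit vectors
#' `e_r` and `e_theta` in the axisymmetric frame), secondary fibrils
#' approximate an isotropic background over seven directions. Weights are
#' normalised so that the uniaxial tangent stiffness of the assembled
#' network along a primary direction at zero strain equals `E_f0`
#' (under a uniaxial strain state, the tangent is
#' `E_f0 * sum_d w_d a_d^4` over the loaded component `a_d` of each
#' direction `d`).
#'
#' @param primary_weight_ratio Relative density of each primary direction
#'   versus each secondary direction (default 3).
#' @return A `fibril_network_layout` with matrix `directions` (rows are
#'   unit vectors in (r, z, theta)), numeric `weights`, and a logical
#'   `primary` flag per direction.
#' @export
fibril_network_layout <- function(primary_weight_ratio = 3) {
  stopifnot(primary_weight_ratio > 0)
  s2 <- 1 / sqrt(2)
  dirs <- rbind(
    c(1, 0, 0),            # primary e_r
    c(0, 0, 1),            # primary e_theta
    c(1, 0, 0),            # secondary set
    c(0, 1, 0),
    c(0, 0, 1),
    c(s2,  s2, 0),
    c(s2, -s2, 0),
    c(0,  s2, s2),
    c(0, -s2, s2))
  primary <- c(TRUE, TRUE, rep(FALSE, 7))
  w <- ifelse(primary, primary_weight_ratio, 1)
  # normalise so the zero-strain uniaxial tangent along e_r equals E_f0
  w <- w / sum(w * dirs[, 1]^4)
  structure(list(directions = dirs, weights = w, primary = primary,
                 primary_weight_ratio = primary_weight_ratio),
            class = "fibril_network_layout")
}

#' Cauchy stress of the assembled fibril network at finite strain
#'
#' Each direction's fibril strain is the logarithmic strain of a material
#' line element, `log |F a|`; tension-only stress from
#' [fibril_stress_update()] acts along the deformed (normalised) direction
#' and is weighted by the layout weights.
#'
#' @param F 3x3 deformation gradient.
#' @param dt Time step \[s\].
#' @param states List of [fibril_state()], one per layout direction.
#' @param layout A [fibril_network_layout()].
#' @param params A [material_params()].
#' @return List with 3x3 Cauchy stress `sigma` \[MPa\] and updated
#'   `states`.
#' @export
fibril_network_stress <- function(F, dt, states, layout, params) {
  stopifnot(inherits(layout, "fibril_network_layout"),
            length(states) == nrow(layout$directions))
  sigma <- matrix(0, 3, 3)
  J <- det(F)
  for (d in seq_len(nrow(layout$directions))) {
    a <- layout$directions[d, ]
    fa <- as.numeric(F %*% a)
    lam <- sqrt(sum(fa^2))
    eps_f <- log(lam)
    upd <- fibril_stress_update(eps_f, dt, states[[d]], params)
    states[[d]] <- upd$state
    if (upd$sigma_f != 0) {
      m <- fa / lam
      sigma <- sigma + (layout$weights[d] * upd$sigma_f) * tcrossprod(m)
    }
  }
  list(sigma = sigma, states = states)
}
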