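#' Strain energy density of the damage material
#'
#' Evaluates the uncoupled strain energy: Veronda-Westmann ground substance in
#' the deviatoric invariants, fiber energy obtained by integrating the
#' piecewise exponential-linear fiber stress with `F2(1) = 0`, and the
#' volumetric penalty `K/2 (ln J)^2`. Fibers store no energy in compression
#' (`lambda_tilde <= 1`).
#'
#' @param state a [deformation_state()].
#' @param params a [material_params()] object; its `fiber_dir` defines the
#'   fiber family.
#' @return Energy density in MPa.
#' @export
strain_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "cdm_material"))
  cpp_strain_energy(state$F, params$fiber_dir, as_pars_vec(params))
}

#' Undamaged Cauchy stress
#'
#' Computes the effective (undamaged) Cauchy stress: the deviatoric
#' push-forward of the isochoric energy derivatives for ground substance and
#' fibers, plus the volumetric pressure `K ln(J)/J I`. The fiber contribution
#' uses the `lambda_tilde * dF2/dlambda_tilde` form directly, so it is exactly
#' zero for `lambda_tilde <= 1`.
#'
#' @inheritParams strain_energy
#' @return A symmetric 3x3 stress tensor in MPa.
#' @export
cauchy_stress_undamaged <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "cdm_material"))
  cpp_cauchy_stress(state$F, params$fiber_dir, as_pars_vec(params))
}

#' Damage criterion value
#'
#' Evaluates the scalar damage driver: either the von Mises stress of the
#' undamaged Cauchy stress deviator, or the maximum principal value of the
#' total Lagrange strain.
#'
#' @param state a [deformation_state()].
#' @param sigma0 the undamaged Cauchy stress for this state (3x3, MPa);
#'   required for the von Mises criterion.
#' @param which `"von_mises"` or `"max_normal_strain"`.
#' @return Criterion value (MPa or strain).
#' @export
damage_criterion <- function(state, sigma0 = NULL,
                             which = c("von_mises", "max_normal_strain")) {
  which <- match.arg(which)
  if (which == "von_mises") {
    stopifnot(is.matrix(sigma0), all(dim(sigma0) == c(3, 3)))
    cpp_von_mises(sigma0)
  } else {
    max(eigen(state$E, symmetric = TRUE, only.values = TRUE)$values)
  }
}

#' Damage as a function of the criterion history maximum
#'
#' Quintic-smoothstep cumulative distribution: zero below `mu_min`, `D_max`
#' above `mu_max`, and `D_max * x^3 (6 x^2 - 15 x + 10)` in between with
#' `x = (xi - mu_min) / (mu_max - mu_min)`. The middle branch is scaled by
#' `D_max` so the function is continuous at `mu_max`; it has zero slope at
#' both thresholds.
#'
#' @param xi_max criterion history maximum (>= 0), possibly a vector.
#' @param dp a [damage_params()] object.
#' @return Damage value(s) in `[0, D_max]`.
#' @export
damage_cdf <- function(xi_max, dp) {
  stopifnot(inherits(dp, "cdm_damage"))
  if (dp$mu_max <= dp$mu_min) stop("mu_max must exceed mu_min")
  vapply(xi_max, cpp_damage_cdf, numeric(1),
         mu_min = dp$mu_min, mu_max = dp$mu_max, D_max = dp$D_max)
}

#' Apply scalar damage to a stress tensor
#'
#' The damaged Cauchy stress scales the effective undamaged stress by
#' `(1 - D)`. `D >= 1` (total failure) is outside the model and raises an
#' error.
#'
#' @param sigma0 undamaged Cauchy stress (3x3, MPa).
#' @param D scalar damage in `[0, 1)`.
#' @return Damaged stress tensor.
#' @export
apply_damage <- function(sigma0, D) {
  if (!is.numeric(D) || length(D) != 1 || D < 0 || D >= 1)
    stop("D must be a scalar in [0, 1); the model never reaches total failure")
  (1 - D) * sigma0
}

#' Irreversible damage state update
#'
#' Damage depends on the running maximum of the criterion over the loading
#' history: the state never heals, so `D` is nondecreasing and stays constant
#' during unloading.
#'
#' @param prev previous state, a list with `xi_max` and `D` (use
#'   `damage_state()` for the virgin state).
#' @param xi_now criterion value at the current configuration.
#' @param dp a [damage_params()] object.
#' @return Updated state (list with `xi_max`, `D`).
#' @export
update_damage_state <- function(prev, xi_now, dp) {
  xi_max <- max(prev$xi_max, xi_now)
  structure(list(xi_max = xi_max, D = damage_cdf(xi_max, dp)),
            class = "damage_state")
}

#' Virgin damage state
#' @return A `damage_state` with `xi_max = 0`, `D = 0`.
#' @export
damage_state <- function() {
  structure(list(xi_max = 0, D = 0), class = "damage_state")
}
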