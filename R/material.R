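#' Transversely isotropic hyperelastic material parameters
#'
#' Constructs the parameter set of the damage material: a Veronda-Westmann
#' ground substance (`C1` in MPa, `C2` dimensionless), a piecewise
#' exponential-linear fiber network (`C3` MPa, `C4` dimensionless, `C5` MPa
#' fiber modulus, transition stretch `lambda_m`), a volumetric penalty with
#' bulk modulus `K` (MPa), and the reference fiber direction. The linear-branch
#' offset `C6` is always derived from the other constants via [compute_C6()]
#' so that the fiber stress is continuous at `lambda_m`; it cannot be supplied.
#'
#' @param C1,C2 Veronda-Westmann ground-substance coefficients (`C1` > 0 MPa).
#' @param C3,C4 fiber toe-region coefficients (`C3` > 0 MPa, `C4` > 0).
#' @param C5 fiber modulus in the linear region (MPa, > 0).
#' @param lambda_m transition stretch between toe and linear fiber response
#'   (> 1).
#' @param K bulk modulus in MPa; the default 1000 MPa enforces
#'   near-incompressibility relative to tissue-scale moduli.
#' @param fiber_dir reference fiber direction, a length-3 vector (normalized
#'   internally).
#' @return An object of class `cdm_material`.
#' @seealso [damage_params()], [compute_C6()]
#' @export
#' @examples
#' mp <- material_params(C1 = 0.78, C2 = 1.20, C3 = 0.43, C4 = 40.83,
#'                       C5 = 119.63, lambda_m = 1.048)
#' mp$C6
material_params <- function(C1, C2, C3, C4, C5, lambda_m, K = 1000,
                            fiber_dir = c(0, 1, 0)) {
  stopifnot(is.numeric(C1), is.numeric(C2), is.numeric(C3), is.numeric(C4),
            is.numeric(C5), is.numeric(lambda_m), is.numeric(K))
  if (C1 <= 0 || C3 <= 0 || C5 <= 0 || K <= 0)
    stop("C1, C3, C5 and K must be positive")
  if (C4 <= 0) stop("C4 must be positive")
  if (lambda_m <= 1) stop("lambda_m must exceed 1")
  fiber_dir <- as.numeric(fiber_dir)
  if (length(fiber_dir) != 3 || sum(fiber_dir^2) == 0)
    stop("fiber_dir must be a nonzero 3-vector")
  fiber_dir <- fiber_dir / sqrt(sum(fiber_dir^2))
  mp <- list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
             C6 = compute_C6(C3, C4, C5, lambda_m),
             lambda_m = lambda_m, K = K, fiber_dir = fiber_dir)
  class(mp) <- "cdm_material"
  mp
}

#' @export
print.cdm_material <- function(x, ...) {
  cat("Transversely isotropic hyperelastic damage material\n")
  cat(sprintf("  ground substance: C1 = %.4g MPa, C2 = %.4g\n", x$C1, x$C2))
  cat(sprintf("  fibers: C3 = %.4g MPa, C4 = %.4g, C5 = %.4g MPa, C6 = %.4g MPa\n",
              x$C3, x$C4, x$C5, x$C6))
  cat(sprintf("  lambda_m = %.4g, K = %.4g MPa\n", x$lambda_m, x$K))
  cat(sprintf("  fiber direction: (%.3g, %.3g, %.3g)\n",
              x$fiber_dir[1], x$fiber_dir[2], x$fiber_dir[3]))
  invisible(x)
}

#' Linear-branch offset ensuring fiber stress continuity
#'
#' The fiber law is exponential below the transition stretch and linear above
#' it; `C6` equates the two branches at `lambda_m`:
#' `C6 = C3 * (exp(C4 * (lambda_m - 1)) - 1) - C5 * lambda_m`.
#'
#' @param C3,C4,C5 fiber coefficients (see [material_params()]).
#' @param lambda_m transition stretch (> 1).
#' @return `C6` in MPa (typically negative).
#' @export
compute_C6 <- function(C3, C4, C5, lambda_m) {
  stopifnot(lambda_m > 1)
  C3 * (exp(C4 * (lambda_m - 1)) - 1) - C5 * lambda_m
}

#' Damage evolution parameters
#'
#' Parameters of the quintic-smoothstep damage law. The damage criterion is
#' either the von Mises stress of the undamaged Cauchy stress (units MPa) or
#' the maximum normal Lagrange strain (dimensionless); `mu_min` and `mu_max`
#' are the criterion values at damage onset and saturation, and `D_max` is the
#' saturation damage, kept below 1 so the material never loses all load
#' carrying capacity.
#'
#' @param criterion `"von_mises"` or `"max_normal_strain"`.
#' @param mu_min,mu_max onset and saturation thresholds in criterion units
#'   (`mu_max > mu_min >= 0`).
#' @param D_max maximum damage, in `[0, 1)`.
#' @return An object of class `cdm_damage`.
#' @export
#' @examples
#' damage_params("von_mises", mu_min = 8.83, mu_max = 43.66, D_max = 0.58)
damage_params <- function(criterion = c("von_mises", "max_normal_strain"),
                          mu_min, mu_max, D_max) {
  criterion <- match.arg(criterion)
  if (!is.numeric(mu_min) || !is.numeric(mu_max) || mu_min < 0)
    stop("mu_min must be >= 0")
  if (mu_max <= mu_min) stop("mu_max must exceed mu_min")
  if (D_max < 0 || D_max >= 1) stop("D_max must lie in [0, 1)")
  dp <- list(criterion = criterion, mu_min = mu_min, mu_max = mu_max,
             D_max = D_max)
  class(dp) <- "cdm_damage"
  dp
}

#' @export
print.cdm_damage <- function(x, ...) {
  unit <- if (x$criterion == "von_mises") "MPa" else "(strain)"
  cat(sprintf("Damage law: %s criterion, mu_min = %.4g %s, mu_max = %.4g %s, D_max = %.3g\n",
              x$criterion, x$mu_min, unit, x$mu_max, unit, x$D_max))
  invisible(x)
}

# internal: flat parameter vector for the compiled kernels
as_pars_vec <- function(mp) {
  c(mp$C1, mp$C2, mp$C3, mp$C4, mp$C5, mp$C6, mp$lambda_m, mp$K)
}

# internal: flat damage vector; criterion coded 0 = von Mises, 1 = max normal strain
as_dp_vec <- function(dp) {
  c(if (dp$criterion == "von_mises") 0 else 1, dp$mu_min, dp$mu_max, dp$D_max)
}

# internal: damage switched off
no_damage <- function() {
  structure(list(criterion = "von_mises", mu_min = 1e30, mu_max = 2e30,
                 D_max = 0), class = "cdm_damage")
}

#' Kinematic state at a material point
#'
#' Builds the deformation state derived from a deformation gradient `F`:
#' the volume ratio `J`, the deviatoric right Cauchy-Green tensor and its
#' invariants, the deviatoric fiber stretch, and the Lagrange strain
#' `E = (F'F - I)/2`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param fiber_dir reference fiber direction (length-3, normalized
#'   internally).
#' @return An object of class `deformation_state` with fields `F`, `J`,
#'   `C_tilde`, `I1_tilde`, `I2_tilde`, `lambda_tilde`, `E`.
#' @export
#' @examples
#' st <- deformation_state(diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1))),
#'                         fiber_dir = c(1, 0, 0))
#' st$lambda_tilde
deformation_state <- function(F, fiber_dir = c(0, 1, 0)) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("deformation gradient has non-positive determinant")
  fiber_dir <- as.numeric(fiber_dir)
  fiber_dir <- fiber_dir / sqrt(sum(fiber_dir^2))
  Ct <- J^(-2 / 3) * crossprod(F)
  I1 <- sum(diag(Ct))
  I2 <- 0.5 * (I1^2 - sum(diag(Ct %*% Ct)))
  st <- list(F = F, J = J, C_tilde = Ct, I1_tilde = I1, I2_tilde = I2,
             lambda_tilde = sqrt(drop(fiber_dir %*% Ct %*% fiber_dir)),
             E = 0.5 * (crossprod(F) - diag(3)),
             fiber_dir = fiber_dir)
  class(st) <- "deformation_state"
  st
}
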