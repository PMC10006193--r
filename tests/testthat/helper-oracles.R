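# Independent oracles used across the suite.

# Cauchy stress by central-difference differentiation of the strain energy:
# P = dPsi/dF, sigma = P F' / J. Independent of the analytic stress path.
numeric_cauchy_stress <- function(F, params, h = 1e-6) {
  st <- function(Fm) strain_energy(deformation_state(Fm), params)
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (st(Fp) - st(Fm)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# random deformation gradient: isochoric distortion plus a volumetric part
random_state <- function(sd = 0.08) {
  repeat {
    A <- matrix(rnorm(9, sd = sd), 3, 3)
    F <- (diag(3) + A) * exp(rnorm(1, sd = 0.01))
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# quadrature oracle for the fiber energy (integrate g(s)/s with base R)
fiber_energy_oracle <- function(lam, params) {
  if (lam <= 1) return(0)
  g <- function(s) vapply(s, function(si) {
    if (si <= 1) 0
    else if (si < params$lambda_m) params$C3 * (exp(params$C4 * (si - 1)) - 1)
    else params$C5 * si + params$C6
  }, numeric(1))
  stats::integrate(function(s) g(s) / s, 1, lam, rel.tol = 1e-12)$value
}

# typical adult human meniscus elastic constants (fitted averages) used as a
# realistic exercise material
average_material <- function(fiber_dir = c(0, 1, 0)) {
  material_params(C1 = 0.78, C2 = 1.20, C3 = 0.43, C4 = 40.83, C5 = 119.63,
                  lambda_m = 1.048, fiber_dir = fiber_dir)
}

# straight-bar variant of the coupon (grip width = gauge width): homogeneous
# uniaxial-stress states are exact solutions on it
bar_geometry <- function(width = 0.6, half_length = 1.0, thickness = 0.5) {
  g <- dogbone_geometry("longitudinal")
  g$gauge_half_width <- width
  g$grip_half_width <- width
  g$gauge_half_length <- half_length * 0.6
  g$fillet_height <- half_length * 0.2
  g$grip_height <- half_length * 0.2
  g$half_thickness <- thickness
  g$half_length <- half_length
  g$gauge_length <- 2 * half_length
  g$area <- 4 * width * thickness
  g
}
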