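#' Sampled tensile curve with geometry metadata
#'
#' Grip-to-grip stretch versus axial force for one coupon, with the metadata
#' needed to convert between force and nominal stress. `area` is the
#' full-coupon reference cross-sectional area in mm^2 (forces are full-coupon
#' forces, i.e. 4x the 1/8-symmetry model force).
#'
#' @param stretch strictly increasing grip-to-grip stretch values starting at 1.
#' @param force axial force in N; `force[1]` must be ~0.
#' @param orientation `"longitudinal"` or `"transverse"` (loading relative to
#'   the preferred fiber direction).
#' @param gauge_length initial grip-to-grip length in mm.
#' @param area reference cross-sectional area in mm^2.
#' @return An object of class `tensile_curve` (a data frame with attributes).
#' @export
tensile_curve <- function(stretch, force,
                          orientation = c("longitudinal", "transverse"),
                          gauge_length, area) {
  orientation <- match.arg(orientation)
  stretch <- as.numeric(stretch); force <- as.numeric(force)
  if (length(stretch) != length(force)) stop("stretch and force lengths differ")
  if (any(diff(stretch) <= 0)) {
    bad <- which(diff(stretch) <= 0)[1] + 1
    stop(sprintf("stretch must be strictly increasing (row %d)", bad))
  }
  if (abs(stretch[1] - 1) > 1e-8) stop("stretch must start at 1")
  if (abs(force[1]) > 1e-6 * max(abs(force), 1e-12))
    stop("force must start at 0")
  cv <- data.frame(stretch = stretch, force = force)
  attr(cv, "orientation") <- orientation
  attr(cv, "gauge_length") <- gauge_length
  attr(cv, "area") <- area
  class(cv) <- c("tensile_curve", "data.frame")
  cv
}

#' @export
print.tensile_curve <- function(x, ...) {
  u <- locate_uts(x)
  cat(sprintf("Tensile curve (%s): %d samples, grip-to-grip stretch 1..%.3f\n",
              attr(x, "orientation"), nrow(x), max(x$stretch)))
  cat(sprintf("  ultimate force %.4g N at stretch %.4g\n", u$force, u$stretch))
  cat(sprintf("  gauge length %.3g mm, area %.3g mm^2\n",
              attr(x, "gauge_length"), attr(x, "area")))
  invisible(x)
}

# internal: orientation -> reference fiber direction in the lab frame
# (loading along y; transverse coupons carry fibers along the in-plane width
# axis x)
orientation_fiber <- function(orientation, fiber_dir = NULL) {
  if (!is.null(fiber_dir)) return(fiber_dir / sqrt(sum(fiber_dir^2)))
  if (orientation == "longitudinal") c(0, 1, 0) else c(1, 0, 0)
}

#' Homogeneous uniaxial-stress tensile simulation
#'
#' Drives the damage material through a prescribed axial stretch history under
#' uniaxial stress: at every step the two lateral stretches are solved by
#' Newton iteration so that the lateral Cauchy stresses vanish (they are
#' independent unknowns because a fiber family transverse to the load axis
#' breaks axisymmetry). Damage is updated once per converged step from the
#' history maximum of the criterion, with internal sub-stepping whenever the
#' damage increment would exceed `dD_step`.
#'
#' @param params a [material_params()].
#' @param dp a [damage_params()], or `NULL` to disable damage.
#' @param orientation `"longitudinal"` (fibers along the load axis) or
#'   `"transverse"` (fibers along the width axis).
#' @param stretch_grid increasing axial stretch values starting at 1.
#' @param fiber_dir optional explicit fiber direction overriding
#'   `orientation`.
#' @param tol Newton tolerance on the lateral stress residual (MPa).
#' @param dD_step largest admissible damage increment per step.
#' @return An object of class `uniaxial_solution`: a data frame with columns
#'   `stretch`, `lambda_x`, `lambda_z`, `J`, `sigma0_axial`, `sigma_axial`,
#'   `nominal_axial` (first Piola-Kirchhoff, MPa), `xi`, `D`, `converged`,
#'   plus attributes `orientation` and `terminated`.
#' @export
simulate_uniaxial <- function(params, dp, orientation = c("longitudinal",
                                                          "transverse"),
                              stretch_grid, fiber_dir = NULL, tol = 1e-8,
                              dD_step = 0.05) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(params, "cdm_material"))
  if (is.null(dp)) dp <- no_damage()
  stretch_grid <- as.numeric(stretch_grid)
  if (abs(stretch_grid[1] - 1) > 1e-12 || any(diff(stretch_grid) <= 0))
    stop("stretch_grid must increase from 1")
  a0 <- orientation_fiber(orientation, fiber_dir)
  m <- cpp_simulate_uniaxial(stretch_grid, a0, as_pars_vec(params),
                             as_dp_vec(dp), tol = tol, dD_step = dD_step)
  sol <- as.data.frame(m)
  names(sol) <- c("stretch", "lambda_x", "lambda_z", "J", "sigma0_axial",
                  "sigma_axial", "nominal_axial", "xi", "D", "converged")
  sol$converged <- sol$converged > 0.5
  attr(sol, "orientation") <- orientation
  attr(sol, "terminated") <- !all(sol$converged)
  class(sol) <- c("uniaxial_solution", "data.frame")
  sol
}

#' Convert a uniaxial solution to a force-stretch curve
#'
#' Forces are nominal axial stress times the reference cross-sectional area,
#' mirroring the conversion of experimental force-displacement data with
#' initial length and initial area.
#'
#' @param sol a [simulate_uniaxial()] result (converged part is used).
#' @param geometry a list with `gauge_length` (mm) and `area` (mm^2, the
#'   full-coupon area the forces should refer to).
#' @return A [tensile_curve()].
#' @export
curve_from_solution <- function(sol, geometry) {
  stopifnot(inherits(sol, "uniaxial_solution"))
  keep <- sol$converged
  tensile_curve(sol$stretch[keep], sol$nominal_axial[keep] * geometry$area,
                orientation = attr(sol, "orientation"),
                gauge_length = geometry$gauge_length, area = geometry$area)
}

#' Ultimate tensile point of a curve
#'
#' Returns the global force maximum and its stretch; ties are broken by the
#' earliest stretch. A curve whose maximum sits at the last sample has no
#' interior peak and is flagged.
#'
#' @param curve a [tensile_curve()] (or any data frame with `stretch`,
#'   `force`), at least 3 points.
#' @return A list with `force` (N), `stretch`, `index`, and `monotone`
#'   (TRUE when no interior maximum exists).
#' @export
locate_uts <- function(curve) {
  if (nrow(curve) < 3) stop("curve needs at least 3 points")
  idx <- which(curve$force >= max(curve$force) - 1e-12 * max(abs(curve$force), 1e-30))[1]
  list(force = curve$force[idx], stretch = curve$stretch[idx], index = idx,
       monotone = idx == nrow(curve))
}
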