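#' Surface element faces of the DIC-imaged coupon face
#'
#' Triangular element faces lying on the z-max surface of the 1/8 model (the
#' face a planar DIC system images), with reference centroids and areas.
#'
#' @param mesh an `fe_mesh`.
#' @return A data frame with columns `elem` (1-based element index), `cx`,
#'   `cy` (reference centroid, mm), `area` (mm^2), `layer` (y-layer id).
#' @export
surface_faces <- function(mesh) {
  zmax <- max(mesh$nodes[, 3])
  on_surf <- abs(mesh$nodes[, 3] - zmax) < 1e-9
  faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  out <- list()
  for (f in 1:4) {
    tri <- mesh$tets[, faces[f, ]] + 1L
    hit <- on_surf[tri[, 1]] & on_surf[tri[, 2]] & on_surf[tri[, 3]]
    if (!any(hit)) next
    a <- mesh$nodes[tri[hit, 1], , drop = FALSE]
    b <- mesh$nodes[tri[hit, 2], , drop = FALSE]
    c_ <- mesh$nodes[tri[hit, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    out[[length(out) + 1]] <- data.frame(
      elem = which(hit),
      cx = (a[, 1] + b[, 1] + c_[, 1]) / 3,
      cy = (a[, 2] + b[, 2] + c_[, 2]) / 3,
      area = 0.5 * sqrt(rowSums(cr^2)),
      layer = mesh$elem_layer[hit])
  }
  do.call(rbind, out)
}

# internal: pull (mesh, damage vector, fields provider) out of an fe_solution
# or a list(mesh = , damage = ) fixture
damage_view <- function(x, step = NULL) {
  if (inherits(x, "fe_solution")) {
    if (is.null(step)) step <- uts_step(x)
    list(mesh = x$mesh, damage = x$steps[[step]]$D, step = step, sol = x)
  } else if (is.list(x) && !is.null(x$mesh) && !is.null(x$damage)) {
    list(mesh = x$mesh, damage = x$damage, step = NULL, sol = NULL)
  } else stop("expected an fe_solution or a list(mesh =, damage =)")
}

#' Locate the tear region of interest
#'
#' Finds the y-layer whose volume-averaged element damage is greatest (the
#' line of action of the damage concentration; ties resolved toward the
#' lowest y and flagged) and builds the ROI as the surface faces within one
#' element layer above and below it, spanning the full coupon width.
#'
#' @param x an `fe_solution` or a `list(mesh =, damage =)` fixture.
#' @param step step index (default: the UTS step, i.e. maximum reaction).
#' @return A list of class `tear_roi`: `faces` (surface-face table), `layers`,
#'   `line_of_action` (mm), `band_height` (mm), `ambiguous` flag.
#' @export
locate_roi <- function(x, step = NULL) {
  v <- damage_view(x, step)
  if (all(v$damage <= 0))
    stop("damage field is identically zero; check the damage parameters")
  vol <- abs(tet_volumes(v$mesh$nodes, v$mesh$tets))
  layer_D <- tapply(v$damage * vol, v$mesh$elem_layer, sum) /
    tapply(vol, v$mesh$elem_layer, sum)
  lids <- as.integer(names(layer_D))
  best <- max(layer_D)
  ambiguous <- sum(layer_D >= best - 1e-12) > 1
  lstar <- min(lids[layer_D >= best - 1e-12])
  layers <- intersect((lstar - 1):(lstar + 1), lids)
  sf <- surface_faces(v$mesh)
  roi <- list(faces = sf[sf$layer %in% layers, , drop = FALSE],
              layers = layers,
              line_of_action = mean(v$mesh$layer_y[lstar, ]),
              band_height = sum(v$mesh$layer_y[layers, 2] -
                                v$mesh$layer_y[layers, 1]),
              ambiguous = ambiguous)
  class(roi) <- "tear_roi"
  roi
}

#' ROI-averaged surface strains at a step
#'
#' Area-weighted averages of the in-plane Lagrange strain components over the
#' ROI surface faces, together with per-face principal values (averaged, as a
#' DIC logfile average would be) and the in-plane maximum shear strain
#' `gamma_max = E1 - E2` (the diameter of the in-plane Mohr circle).
#'
#' @param sol an `fe_solution`.
#' @param roi a [locate_roi()] result.
#' @param step step index (default: UTS step).
#' @return A list of class `roi_strains` with `E_yy`, `E_xx`, `E_xy`, `E1`,
#'   `E2`, `gamma_max`, `mean_D`, `n_faces`.
#' @export
roi_strains <- function(sol, roi, step = NULL) {
  stopifnot(inherits(sol, "fe_solution"), inherits(roi, "tear_roi"))
  if (nrow(roi$faces) == 0) stop("ROI is empty")
  if (is.null(step)) step <- uts_step(sol)
  fl <- element_fields(sol, step)
  f <- roi$faces
  w <- f$area / sum(f$area)
  Exx <- fl$Exx[f$elem]; Eyy <- fl$Eyy[f$elem]; Exy <- fl$Exy[f$elem]
  # principal values of the in-plane 2x2 block, per face
  m <- (Exx + Eyy) / 2
  r <- sqrt(((Exx - Eyy) / 2)^2 + Exy^2)
  out <- list(E_yy = sum(w * Eyy), E_xx = sum(w * Exx), E_xy = sum(w * Exy),
              E1 = sum(w * (m + r)), E2 = sum(w * (m - r)),
              gamma_max = sum(w * 2 * r),
              mean_D = sum(w * fl$D[f$elem]), n_faces = nrow(f), step = step)
  class(out) <- "roi_strains"
  out
}

#' @export
print.roi_strains <- function(x, ...) {
  cat(sprintf("ROI surface strains (step %s, %d faces):\n",
              x$step, x$n_faces))
  cat(sprintf("  E_yy = %.4f  E_xx = %.4f  E_xy = %.4f\n", x$E_yy, x$E_xx, x$E_xy))
  cat(sprintf("  E1 = %.4f  E2 = %.4f  gamma_max = %.4f  mean D = %.3f\n",
              x$E1, x$E2, x$gamma_max, x$mean_D))
  invisible(x)
}

# internal: principal-axis angle (degrees from the width axis, i.e. from
# perpendicular-to-load) of a weighted 2D point set
principal_angle <- function(xc, yc, w) {
  w <- w / sum(w)
  mx <- sum(w * xc); my <- sum(w * yc)
  sxx <- sum(w * (xc - mx)^2); syy <- sum(w * (yc - my)^2)
  sxy <- sum(w * (xc - mx) * (yc - my))
  ang <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  # fold into (-90, 90]
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Tear angle from the surface damage band
#'
#' Thresholds the surface damage field at a fraction of its maximum and fits
#' the dominant oriented band by the principal axis of the face centroids
#' (area-weighted). The angle is measured from perpendicular-to-load: 0
#' degrees is a tear straight across the coupon, 90 degrees is parallel to
#' the loading axis. Because tears can change direction at the coupon
#' midline, the band is additionally split at its median width coordinate
#' into an outer half (near the free edge, where tears initiate at the
#' fillet) and an inner half (near the coupon center axis).
#'
#' @param x an `fe_solution` or `list(mesh =, damage =)` fixture.
#' @param step step index (default UTS step or later; any step with nonzero
#'   damage).
#' @param threshold fraction of the maximum surface damage (default 0.8).
#' @return A list of class `tear_angle` with `angle` (whole band), `outer`,
#'   `inner` (degrees), `n_faces`, `threshold`.
#' @export
tear_angle <- function(x, step = NULL, threshold = 0.8) {
  v <- damage_view(x, step)
  if (all(v$damage <= 0)) stop("damage field is identically zero")
  sf <- surface_faces(v$mesh)
  sf$D <- v$damage[sf$elem]
  # aggregate triangle faces by their parent grid cell before thresholding:
  # sub-cell stress oscillations of the locking-prone linear tets are
  # numerical noise, and the fixed hex-to-tet template places triangle
  # centroids on a diagonal lattice that would bias the principal axis
  f <- if (!is.null(v$mesh$elem_cell)) {
    cell <- v$mesh$elem_cell[sf$elem]
    w <- tapply(sf$area, cell, sum)
    data.frame(cx = tapply(sf$area * sf$cx, cell, sum) / w,
               cy = tapply(sf$area * sf$cy, cell, sum) / w,
               area = as.numeric(w),
               D = as.numeric(tapply(sf$area * sf$D, cell, sum) / w))
  } else sf[, c("cx", "cy", "area", "D")]
  f <- f[f$D >= threshold * max(f$D), , drop = FALSE]
  if (nrow(f) < 3)
    stop("fewer than 3 surface faces above the damage threshold")
  ang <- principal_angle(f$cx, f$cy, f$area)
  xmed <- stats::median(f$cx)
  outer <- f[f$cx >= xmed, , drop = FALSE]
  inner <- f[f$cx < xmed, , drop = FALSE]
  res <- list(
    angle = ang,
    outer = if (nrow(outer) >= 3) principal_angle(outer$cx, outer$cy, outer$area) else NA_real_,
    inner = if (nrow(inner) >= 3) principal_angle(inner$cx, inner$cy, inner$area) else NA_real_,
    n_faces = nrow(f), threshold = threshold)
  class(res) <- "tear_angle"
  res
}

#' @export
print.tear_angle <- function(x, ...) {
  cat(sprintf("Tear angle: %.1f deg (outer half %.1f, inner half %.1f; %d faces at %.0f%% threshold)\n",
              x$angle, x$outer, x$inner, x$n_faces, 100 * x$threshold))
  invisible(x)
}

#' Mesh convergence study of the ROI tensile strain
#'
#' Solves the same loading on a sequence of refined meshes and tabulates the
#' ROI-averaged tensile strain `E_yy`, flagging the monotone-increase-then-
#' plateau behavior expected of the refinement (plateau: last increment below
#' 25% of the first increment).
#'
#' @param meshes list of `fe_mesh` objects, coarse to fine (>= 3).
#' @param params a [material_params()].
#' @param dp a [damage_params()] or `NULL`.
#' @param target_stretch grip-to-grip stretch to apply.
#' @param ... passed to [solve_quasistatic()].
#' @return A data frame (class `mesh_convergence`) with `elements`,
#'   `roi_Eyy`, `max_D`, `runtime_s`, plus attributes `monotone` and
#'   `plateau`.
#' @export
mesh_convergence_report <- function(meshes, params, dp, target_stretch, ...) {
  stopifnot(length(meshes) >= 3)
  rows <- lapply(meshes, function(msh) {
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_quasistatic(msh, params, dp, target_stretch, ...)
    rt <- proc.time()[["elapsed"]] - t0
    step <- length(sol$steps)
    roi <- tryCatch(locate_roi(sol, step), error = function(e) NULL)
    if (is.null(roi)) {
      # no damage developed: place the ROI at the layer of peak tensile strain
      fl <- element_fields(sol, step)
      vol <- abs(tet_volumes(msh$nodes, msh$tets))
      layer_E <- tapply(fl$Eyy * vol, msh$elem_layer, sum) /
        tapply(vol, msh$elem_layer, sum)
      lstar <- as.integer(names(layer_E))[which.max(layer_E)]
      fake <- list(mesh = msh, damage = replace(numeric(nrow(msh$tets)),
                                               msh$elem_layer == lstar, 1))
      roi <- locate_roi(fake)
    }
    rs <- roi_strains(sol, roi, step)
    data.frame(elements = n_elements(msh), roi_Eyy = rs$E_yy,
               max_D = max(sol$steps[[step]]$D), runtime_s = rt)
  })
  tab <- do.call(rbind, rows)
  d <- diff(tab$roi_Eyy)
  attr(tab, "monotone") <- all(d > 0)
  attr(tab, "plateau") <- if (abs(d[1]) < 1e-15) TRUE else
    abs(d[length(d)]) < 0.25 * abs(d[1])
  class(tab) <- c("mesh_convergence", "data.frame")
  tab
}
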