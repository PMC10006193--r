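#' Default dogbone coupon geometry (1/8-symmetry model)
#'
#' Dimensions of the 1/8-symmetry dumbbell coupon model, in mm. The loading
#' axis is y, the width axis x, the thickness axis z; the model spans half the
#' width, half the thickness and half the grip-to-grip length, with symmetry
#' planes at x = 0, y = 0 and z = 0. The shoulder blends the gauge half-width
#' into the grip half-width with a smooth cosine fillet.
#'
#' @param orientation `"longitudinal"` or `"transverse"`; transverse coupons
#'   are shorter (they reach much larger grip-to-grip stretches).
#' @return A list of class `dogbone_geometry` with fields `gauge_half_width`,
#'   `grip_half_width`, `half_thickness`, `gauge_half_length`,
#'   `fillet_height`, `grip_height`, `half_length`, `gauge_length`
#'   (full grip-to-grip length), and `area` (full-coupon gauge cross-section,
#'   mm^2).
#' @export
dogbone_geometry <- function(orientation = c("longitudinal", "transverse")) {
  orientation <- match.arg(orientation)
  # generous shoulders (punch-cut coupons have no sharp re-entrant corner)
  g <- if (orientation == "longitudinal") {
    list(gauge_half_width = 0.6, grip_half_width = 1.2, half_thickness = 0.5,
         gauge_half_length = 1.2, fillet_height = 1.6, grip_height = 0.4)
  } else {
    # transverse coupons are punched across the fiber field: short and wide
    list(gauge_half_width = 1.2, grip_half_width = 1.8, half_thickness = 0.5,
         gauge_half_length = 0.4, fillet_height = 0.6, grip_height = 0.25)
  }
  g$half_length <- g$gauge_half_length + g$fillet_height + g$grip_height
  g$gauge_length <- 2 * g$half_length
  g$area <- 4 * g$gauge_half_width * g$half_thickness
  g$orientation <- orientation
  class(g) <- "dogbone_geometry"
  g
}

# half-width profile of the dogbone at height y (reference configuration)
dogbone_half_width <- function(y, g) {
  w <- numeric(length(y))
  y1 <- g$gauge_half_length
  y2 <- y1 + g$fillet_height
  w[y <= y1] <- g$gauge_half_width
  mid <- y > y1 & y < y2
  t <- (y[mid] - y1) / g$fillet_height
  w[mid] <- g$gauge_half_width +
    (g$grip_half_width - g$gauge_half_width) * (1 - cos(pi * t)) / 2
  w[y >= y2] <- g$grip_half_width
  w
}

# fixed 6-tet decomposition of a hexahedron along the v0-v7 diagonal;
# vertex bits ordered (x, y, z)
hex_tet_template <- function() {
  rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
        c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7))
}

#' Build the 1/8-symmetry dogbone mesh
#'
#' Structured grid of hexahedral cells, each split into 6 linear tetrahedra
#' with a fixed template (deterministic, reproducible element counts). A band
#' of height `refine_band` (full-coupon units, centered on the coupon
#' mid-plane, so the model band is `[0, refine_band/2]`) is refined by
#' `refine_factor`: the width and thickness axes are subdivided by the factor
#' throughout (the band spans the full width and thickness), the length axis
#' only inside the band, which keeps the mesh conforming.
#'
#' @param geometry a [dogbone_geometry()].
#' @param refine_band refined band height in mm (full coupon; 0 disables).
#' @param refine_factor integer subdivision factor (1 = base mesh).
#' @param base_res base resolution `c(nx, ny, nz)` of the structured grid:
#'   cells across the half-width, along the half-length, and through the
#'   half-thickness.
#' @return An object of class `fe_mesh`: `nodes` (n x 3, mm), `tets`
#'   (m x 4, zero-based), node sets (`grip`, `sym_x`, `sym_y`, `sym_z`;
#'   1-based node indices), `elem_layer` (y-layer id per element),
#'   `elem_band` (logical), `fiber` (m x 3 reference fiber directions),
#'   `layer_y` (y-interval per layer), `geometry`.
#' @export
build_dogbone_mesh <- function(geometry, refine_band = 2.5, refine_factor = 1,
                               base_res = c(8, 10, 2)) {
  stopifnot(inherits(geometry, "dogbone_geometry"),
            refine_factor >= 1, refine_factor == round(refine_factor))
  g <- geometry
  if (g$gauge_half_width <= 0 || g$half_thickness <= 0 || g$half_length <= 0 ||
      g$grip_half_width < g$gauge_half_width)
    stop("degenerate coupon geometry")
  nx <- base_res[1] * refine_factor
  nz <- base_res[3] * refine_factor
  ny0 <- base_res[2]
  band_top <- min(refine_band / 2, g$half_length)

  # y grid: base rows, rows intersecting the band subdivided
  y_base <- seq(0, g$half_length, length.out = ny0 + 1)
  ylines <- c()
  for (j in seq_len(ny0)) {
    lo <- y_base[j]; hi <- y_base[j + 1]
    nsub <- if (refine_factor > 1 && lo < band_top - 1e-12) refine_factor else 1
    ylines <- c(ylines, seq(lo, hi, length.out = nsub + 1)[-(nsub + 1)])
  }
  ylines <- c(ylines, g$half_length)
  ny <- length(ylines) - 1

  xi <- seq(0, 1, length.out = nx + 1)
  zi <- seq(0, g$half_thickness, length.out = nz + 1)
  wy <- dogbone_half_width(ylines, g)

  nid <- function(i, j, k) (k - 1) * (nx + 1) * (ny + 1) + (j - 1) * (nx + 1) + i
  nn <- (nx + 1) * (ny + 1) * (nz + 1)
  nodes <- matrix(0, nn, 3)
  for (k in seq_len(nz + 1)) for (j in seq_len(ny + 1)) {
    idx <- nid(seq_len(nx + 1), j, k)
    nodes[idx, 1] <- xi * wy[j]
    nodes[idx, 2] <- ylines[j]
    nodes[idx, 3] <- zi[k]
  }

  tmpl <- hex_tet_template()
  ne <- nx * ny * nz * 6
  tets <- matrix(0L, ne, 4)
  elem_layer <- integer(ne)
  elem_cell <- integer(ne)
  cell <- 0L
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v <- c(nid(i, j, k),     nid(i + 1, j, k),
           nid(i, j + 1, k), nid(i + 1, j + 1, k),
           nid(i, j, k + 1), nid(i + 1, j, k + 1),
           nid(i, j + 1, k + 1), nid(i + 1, j + 1, k + 1))
    cell <- cell + 1L
    for (t in 1:6) {
      e <- e + 1L
      tets[e, ] <- as.integer(v[tmpl[t, ] + 1] - 1L)  # zero-based
      elem_layer[e] <- j
      elem_cell[e] <- cell
    }
  }

  # enforce positive orientation
  vol6 <- tet_volumes(nodes, tets)
  flip <- vol6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(tet_volumes(nodes, tets) <= 0)) stop("degenerate elements in mesh")

  layer_mid <- (ylines[-1] + ylines[-length(ylines)]) / 2
  fib <- matrix(rep(orientation_fiber(g$orientation), each = ne), ne, 3)

  tolg <- 1e-9
  mesh <- list(
    nodes = nodes, tets = tets,
    grip = which(abs(nodes[, 2] - g$half_length) < tolg),
    sym_x = which(abs(nodes[, 1]) < tolg),
    sym_y = which(abs(nodes[, 2]) < tolg),
    sym_z = which(abs(nodes[, 3]) < tolg),
    elem_layer = elem_layer,
    elem_cell = elem_cell,
    elem_band = layer_mid[elem_layer] < band_top,
    fiber = fib,
    layer_y = cbind(ylines[-length(ylines)], ylines[-1]),
    geometry = g, refine_factor = refine_factor, refine_band = refine_band)
  class(mesh) <- "fe_mesh"
  mesh
}

# signed volumes (in mm^3) of all tets
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1] + 1, , drop = FALSE]
  b <- nodes[tets[, 2] + 1, , drop = FALSE]
  c_ <- nodes[tets[, 3] + 1, , drop = FALSE]
  d <- nodes[tets[, 4] + 1, , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("1/8-symmetry dogbone mesh (%s): %d nodes, %d tetrahedra\n",
              x$geometry$orientation, nrow(x$nodes), nrow(x$tets)))
  cat(sprintf("  refine factor %d, band %.3g mm (%d refined elements)\n",
              x$refine_factor, x$refine_band, sum(x$elem_band)))
  invisible(x)
}

#' Number of elements in a mesh
#' @param mesh an `fe_mesh`.
#' @return Integer element count.
#' @export
n_elements <- function(mesh) nrow(mesh$tets)
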