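#' Quasi-static displacement-driven finite element solve
#'
#' Total-Lagrangian Newton solve of the damage material on linear tetrahedra.
#' Grip-face nodes carry a prescribed axial displacement with free lateral
#' sliding (the rigid-grip limit of a frictionless sliding contact); the three
#' symmetry planes fix their normal displacement. Damage is explicit per load
#' step: each element's damage is frozen at its value from the previous
#' converged step during the Newton iterations and updated from the criterion
#' history maximum once the step converges. Steps are cut back (halved, up to
#' `max_cutbacks` times) on Newton divergence or when the largest element
#' damage increment exceeds `dD_max`; exhaustion returns the solution up to
#' the last converged step with a termination flag, mirroring the premature
#' termination damage localization can cause on coarse meshes.
#'
#' @param mesh an [build_dogbone_mesh()] mesh (`fe_mesh`).
#' @param params a [material_params()] (its `fiber_dir` is ignored; the
#'   mesh carries per-element fiber directions).
#' @param dp a [damage_params()], or `NULL` to disable damage.
#' @param grip_stretch_target target grip-to-grip stretch (> 1).
#' @param n_steps number of nominally equal load steps.
#' @param rtol relative residual tolerance (fraction of the reaction-force
#'   norm); `atol` (N) covers the load-free first steps.
#' @param max_iter Newton iteration cap per step.
#' @param max_cutbacks number of step halvings before giving up.
#' @param dD_max largest admissible element damage increment per step.
#' @param verbose print per-step progress.
#' @return An object of class `fe_solution`: the mesh, per-step records
#'   (`stretch`, nodal displacements `u`, `reaction` (N), element damage `D`,
#'   criterion history maximum `xi_max`, frozen damage `D_frozen`), and a
#'   `status` field (`"completed"` or `"terminated"`).
#' @export
solve_quasistatic <- function(mesh, params, dp, grip_stretch_target,
                              n_steps = 20, rtol = 1e-6, atol = 1e-8,
                              max_iter = 30, max_cutbacks = 8, dD_max = 0.1,
                              verbose = FALSE) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(params, "cdm_material"),
            grip_stretch_target > 1)
  if (is.null(dp)) dp <- no_damage()
  pars <- as_pars_vec(params)
  crit <- if (dp$criterion == "von_mises") 0L else 1L
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$tets)
  L <- mesh$geometry$half_length

  pre <- cpp_fe_precompute(mesh$nodes, mesh$tets)
  G <- pre$G; V0 <- pre$V0

  dof <- function(nodes, comp) 3 * (nodes - 1) + comp
  grip_y <- dof(mesh$grip, 2)
  fixed0 <- c(dof(mesh$sym_x, 1), dof(mesh$sym_y, 2), dof(mesh$sym_z, 3))
  presc <- unique(c(fixed0, grip_y))
  free <- setdiff(seq_len(3 * nn), presc)

  u <- numeric(3 * nn)
  xi_max <- numeric(ne)
  D <- numeric(ne)
  steps <- list()
  status <- "completed"

  newton <- function(u, Dfrozen) {
    for (it in seq_len(max_iter)) {
      fr <- cpp_fe_internal_force(mesh$tets, G, V0, mesh$fiber, pars, u, Dfrozen)
      if (!fr$ok || !all(is.finite(fr$f))) return(NULL)
      r <- fr$f
      rext <- sqrt(sum(r[presc]^2))
      rnorm <- sqrt(sum(r[free]^2))
      if (rnorm <= max(atol, rtol * rext))
        return(list(u = u, reaction = sum(r[grip_y]), rnorm = rnorm, iters = it))
      tg <- cpp_fe_tangent(mesh$tets, G, V0, mesh$fiber, pars, u, Dfrozen)
      if (!tg$ok) return(NULL)
      K <- Matrix::sparseMatrix(i = as.integer(tg$i), j = as.integer(tg$j),
                                x = as.numeric(tg$x), dims = c(3 * nn, 3 * nn))
      du <- tryCatch(
        as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r[free])),
        error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) return(NULL)
      # backtracking line search on the free-residual norm
      s <- 1
      for (ls in 1:6) {
        ut <- u; ut[free] <- ut[free] + s * du
        ft <- cpp_fe_internal_force(mesh$tets, G, V0, mesh$fiber, pars, ut, Dfrozen)
        if (ft$ok && all(is.finite(ft$f)) &&
            sqrt(sum(ft$f[free]^2)) < rnorm * (1 - 0.1 * s) + atol) break
        s <- s / 2
        if (ls == 6) { s <- NA; break }
      }
      if (is.na(s)) { u[free] <- u[free] + du } else { u[free] <- u[free] + s * du }
    }
    # final residual check
    fr <- cpp_fe_internal_force(mesh$tets, G, V0, mesh$fiber, pars, u, Dfrozen)
    if (fr$ok && all(is.finite(fr$f))) {
      r <- fr$f
      if (sqrt(sum(r[free]^2)) <= max(atol, rtol * sqrt(sum(r[presc]^2))))
        return(list(u = u, reaction = sum(r[grip_y]),
                    rnorm = sqrt(sum(r[free]^2)), iters = max_iter))
    }
    NULL
  }

  s_cur <- 1
  ds0 <- (grip_stretch_target - 1) / n_steps
  ds <- ds0
  cutbacks_left <- max_cutbacks
  while (s_cur < grip_stretch_target - 1e-12) {
    s_try <- min(s_cur + ds, grip_stretch_target)
    # predictor: scale the previous displacement field to the new stretch
    # (first step: affine axial stretch), then pin the prescribed dofs
    ut <- if (s_cur > 1 + 1e-12) u * (s_try - 1) / (s_cur - 1) else {
      u0 <- numeric(3 * nn)
      u0[seq(2, 3 * nn, by = 3)] <- (s_try - 1) * mesh$nodes[, 2]
      u0
    }
    ut[presc] <- 0
    ut[grip_y] <- (s_try - 1) * L
    res <- newton(ut, D)
    ok <- !is.null(res)
    if (ok) {
      fields <- cpp_fe_fields(mesh$tets, G, mesh$fiber, pars, res$u, crit)
      xi_new <- pmax(xi_max, fields[, 14])
      D_new <- vapply(xi_new, cpp_damage_cdf, numeric(1),
                      mu_min = dp$mu_min, mu_max = dp$mu_max, D_max = dp$D_max)
      if (max(D_new - D) > dD_max) ok <- FALSE
    }
    if (!ok) {
      if (cutbacks_left <= 0 || ds < 1e-6) { status <- "terminated"; break }
      ds <- ds / 2
      cutbacks_left <- cutbacks_left - 1
      next
    }
    steps[[length(steps) + 1]] <- list(stretch = s_try, u = res$u,
                                       reaction = res$reaction,
                                       D = D_new, xi_max = xi_new,
                                       D_frozen = D)
    if (verbose)
      message(sprintf("step %d: stretch %.4f, reaction %.4g N, max D %.3f, %d iters",
                      length(steps), s_try, res$reaction, max(D_new), res$iters))
    u <- res$u; xi_max <- xi_new; D <- D_new; s_cur <- s_try
    if (ds < ds0) { ds <- min(ds * 1.5, ds0); cutbacks_left <- min(cutbacks_left + 1, max_cutbacks) }
  }

  sol <- list(mesh = mesh, params = params, dp = dp, steps = steps,
              status = status, grip_dofs = grip_y,
              precomp = list(G = G, V0 = V0), criterion = crit)
  class(sol) <- "fe_solution"
  sol
}

#' @export
print.fe_solution <- function(x, ...) {
  ns <- length(x$steps)
  cat(sprintf("FE solution: %d converged steps, status '%s'\n", ns, x$status))
  if (ns > 0) {
    last <- x$steps[[ns]]
    cat(sprintf("  final stretch %.4f, reaction %.4g N, max damage %.3f\n",
                last$stretch, last$reaction, max(last$D)))
  }
  invisible(x)
}

#' Grip reaction force at a converged step
#'
#' Recomputes the internal nodal forces from the stored displacement field
#' (with the damage frozen during that step) and sums the axial components on
#' the grip face. By global equilibrium this equals minus the sum over the
#' opposite symmetry face.
#'
#' @param sol an [solve_quasistatic()] result.
#' @param step step index.
#' @return Axial reaction force of the 1/8 model in N (multiply by 4 for the
#'   full-coupon equivalent).
#' @export
reaction_force <- function(sol, step) {
  stopifnot(inherits(sol, "fe_solution"))
  if (step < 1 || step > length(sol$steps)) stop("no converged step ", step)
  st <- sol$steps[[step]]
  fr <- cpp_fe_internal_force(sol$mesh$tets, sol$precomp$G, sol$precomp$V0,
                              sol$mesh$fiber, as_pars_vec(sol$params),
                              st$u, st$D_frozen)
  if (!fr$ok) stop("stored step could not be re-evaluated")
  sum(fr$f[sol$grip_dofs])
}

#' Per-element fields at a converged step
#'
#' @param sol an `fe_solution`.
#' @param step step index.
#' @return A data frame with Lagrange strain components (`Exx` ... `Exz`),
#'   undamaged stress components (`S0xx` ... `S0xz`), the damaged stress
#'   scale, `J`, the criterion value `xi`, and element damage `D`.
#' @export
element_fields <- function(sol, step) {
  stopifnot(inherits(sol, "fe_solution"))
  if (step < 1 || step > length(sol$steps)) stop("no converged step ", step)
  st <- sol$steps[[step]]
  m <- cpp_fe_fields(sol$mesh$tets, sol$precomp$G, sol$mesh$fiber,
                     as_pars_vec(sol$params), st$u, sol$criterion)
  df <- as.data.frame(m)
  names(df) <- c("Exx", "Eyy", "Ezz", "Exy", "Eyz", "Exz",
                 "S0xx", "S0yy", "S0zz", "S0xy", "S0yz", "S0xz", "J", "xi")
  df$D <- st$D
  df
}

# internal: step with maximum grip reaction (the UTS step)
uts_step <- function(sol) {
  if (length(sol$steps) == 0) stop("solution has no converged steps")
  which.max(vapply(sol$steps, function(s) s$reaction, numeric(1)))
}

#' Grip force-stretch curve of an FE solution
#'
#' @param sol an `fe_solution`.
#' @param full_coupon multiply the 1/8-model reaction by 4 to obtain the
#'   full-coupon equivalent force (default TRUE).
#' @return A [tensile_curve()] (a leading zero-force point at stretch 1 is
#'   included).
#' @export
fe_force_curve <- function(sol, full_coupon = TRUE) {
  stopifnot(inherits(sol, "fe_solution"))
  s <- vapply(sol$steps, function(x) x$stretch, numeric(1))
  f <- vapply(sol$steps, function(x) x$reaction, numeric(1))
  fac <- if (full_coupon) 4 else 1
  g <- sol$mesh$geometry
  tensile_curve(c(1, s), c(0, f * fac), orientation = g$orientation,
                gauge_length = g$gauge_length, area = g$area)
}
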