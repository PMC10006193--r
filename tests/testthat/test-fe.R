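test_that("single-element patch: FE stress equals the constitutive stress", {
  # one regular tetrahedron, affine deformation imposed through nodal
  # displacements; the element stress must equal a direct constitutive
  # evaluation at that deformation gradient
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- matrix(c(0L, 1L, 2L, 3L), 1, 4)
  fib <- matrix(c(0, 1, 0), 1, 3)
  mp <- average_material()
  pars <- meniscusCDM:::as_pars_vec(mp)
  F <- matrix(c(1.08, 0.02, 0, 0.01, 1.11, 0.03, 0, 0.02, 0.95), 3, 3)
  u <- as.numeric(t(nodes %*% t(F) - nodes))  # node-major (x,y,z) triples
  pre <- meniscusCDM:::cpp_fe_precompute(nodes, tets)
  fl <- meniscusCDM:::cpp_fe_fields(tets, pre$G, fib, pars, u, 0L)
  sig <- cauchy_stress_undamaged(deformation_state(F), mp)
  expect_equal(as.numeric(fl[1, 7:12]),
               c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[2, 3],
                 sig[1, 3]), tolerance = 1e-8)
  E <- 0.5 * (t(F) %*% F - diag(3))
  expect_equal(as.numeric(fl[1, 1:6]),
               c(E[1, 1], E[2, 2], E[3, 3], E[1, 2], E[2, 3], E[1, 3]),
               tolerance = 1e-10)
})

test_that("a stretched straight bar reproduces the homogeneous solution", {
  # on a prismatic bar the uniaxial-stress state is an exact solution of the
  # boundary value problem, so the FE fields must be homogeneous and match
  # the material-point driver
  g <- bar_geometry()
  msh <- build_dogbone_mesh(g, refine_factor = 1, base_res = c(3, 4, 2))
  mp <- average_material()
  sol <- solve_quasistatic(msh, mp, NULL, 1.05, n_steps = 5)
  expect_identical(sol$status, "completed")
  el <- element_fields(sol, length(sol$steps))
  ref <- simulate_uniaxial(mp, NULL, "longitudinal", c(1, 1.05))
  expect_equal(max(abs(el$S0yy - ref$sigma0_axial[2])) /
                 abs(ref$sigma0_axial[2]), 0, tolerance = 1e-6)
  expect_lt(diff(range(el$Eyy)), 1e-8)
  # reaction equals nominal stress times the model cross-section
  area_model <- g$gauge_half_width * g$half_thickness
  expect_equal(sol$steps[[length(sol$steps)]]$reaction,
               ref$nominal_axial[2] * area_model, tolerance = 1e-5)
})

test_that("global equilibrium: grip force balances the symmetry face", {
  g <- bar_geometry()
  msh <- build_dogbone_mesh(g, refine_factor = 1, base_res = c(2, 3, 1))
  mp <- average_material()
  sol <- solve_quasistatic(msh, mp, NULL, 1.04, n_steps = 4)
  st <- sol$steps[[length(sol$steps)]]
  fr <- meniscusCDM:::cpp_fe_internal_force(
    msh$tets, sol$precomp$G, sol$precomp$V0, msh$fiber,
    meniscusCDM:::as_pars_vec(mp), st$u, st$D_frozen)
  grip_y <- 3 * (msh$grip - 1) + 2
  base_y <- 3 * (msh$sym_y - 1) + 2
  expect_equal(sum(fr$f[grip_y]), -sum(fr$f[base_y]), tolerance = 1e-8)
  expect_equal(reaction_force(sol, length(sol$steps)), st$reaction,
               tolerance = 1e-12)
  expect_error(reaction_force(sol, 99), "no converged step")
})

test_that("small-stretch response is linear to within a few percent", {
  g <- bar_geometry()
  msh <- build_dogbone_mesh(g, refine_factor = 1, base_res = c(2, 3, 1))
  mp <- average_material()
  r1 <- solve_quasistatic(msh, mp, NULL, 1.001, n_steps = 1)
  r2 <- solve_quasistatic(msh, mp, NULL, 1.002, n_steps = 1)
  f1 <- r1$steps[[1]]$reaction
  f2 <- r2$steps[[1]]$reaction
  expect_equal(f2 / f1, 2, tolerance = 0.05)
})

test_that("reaction work matches stored energy without damage", {
  g <- bar_geometry()
  msh <- build_dogbone_mesh(g, refine_factor = 1, base_res = c(2, 3, 1))
  mp <- average_material()
  sol <- solve_quasistatic(msh, mp, NULL, 1.06, n_steps = 24)
  s <- vapply(sol$steps, `[[`, 0, "stretch")
  f <- vapply(sol$steps, `[[`, 0, "reaction")
  L <- g$half_length
  work <- sum(diff(c(1, s)) * L * (c(0, head(f, -1)) + f) / 2)
  st <- sol$steps[[length(sol$steps)]]
  W <- meniscusCDM:::cpp_fe_total_energy(msh$tets, sol$precomp$G,
                                         sol$precomp$V0, msh$fiber,
                                         meniscusCDM:::as_pars_vec(mp), st$u)
  expect_equal(work, W, tolerance = 0.01)
})

test_that("equilibrium residual is small relative to the external force", {
  g <- dogbone_geometry("longitudinal")
  msh <- build_dogbone_mesh(g, refine_factor = 1)
  tr <- synthetic_truth("longitudinal", "von_mises")
  sol <- solve_quasistatic(msh, tr$params, NULL, 1.04, n_steps = 4)
  st <- sol$steps[[length(sol$steps)]]
  fr <- meniscusCDM:::cpp_fe_internal_force(
    msh$tets, sol$precomp$G, sol$precomp$V0, msh$fiber,
    meniscusCDM:::as_pars_vec(tr$params), st$u, st$D_frozen)
  nn <- nrow(msh$nodes)
  dofs <- seq_len(3 * nn)
  presc <- unique(c(3 * (msh$sym_x - 1) + 1, 3 * (msh$sym_y - 1) + 2,
                    3 * (msh$sym_z - 1) + 3, 3 * (msh$grip - 1) + 2))
  free <- setdiff(dofs, presc)
  expect_lt(sqrt(sum(fr$f[free]^2)), 1e-6 * sqrt(sum(fr$f[presc]^2)))
})

test_that("element damage fields are nondecreasing across steps", {
  g <- dogbone_geometry("longitudinal")
  msh <- build_dogbone_mesh(g, refine_factor = 1)
  tr <- synthetic_truth("longitudinal", "von_mises")
  # damage thresholds scaled to the coarse model's stress level so damage
  # develops within a short run
  dp <- damage_params("von_mises", mu_min = 0.4, mu_max = 1.6, D_max = 0.5)
  sol <- solve_quasistatic(msh, tr$params, dp, 1.10, n_steps = 8)
  expect_gt(max(sol$steps[[length(sol$steps)]]$D), 0)
  Dmat <- vapply(sol$steps, `[[`, numeric(nrow(msh$tets)), "D")
  expect_true(all(apply(Dmat, 1, function(x) all(diff(x) >= -1e-14))))
  expect_equal(sol$steps[[1]]$D_frozen, numeric(nrow(msh$tets)))
})

test_that("an impossible damage-increment bound terminates gracefully", {
  g <- dogbone_geometry("longitudinal")
  msh <- build_dogbone_mesh(g, refine_factor = 1)
  tr <- synthetic_truth("longitudinal", "von_mises")
  dp <- damage_params("von_mises", mu_min = 0.05, mu_max = 0.1, D_max = 0.9)
  sol <- solve_quasistatic(msh, tr$params, dp, 1.2, n_steps = 2,
                           max_cutbacks = 0, dD_max = 1e-9)
  expect_identical(sol$status, "terminated")
})
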