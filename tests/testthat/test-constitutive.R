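test_that("strain energy vanishes in the reference configuration", {
  mp <- average_material()
  st <- deformation_state(diag(3))
  expect_equal(strain_energy(st, mp), 0, tolerance = 1e-14)
  expect_equal(cauchy_stress_undamaged(st, mp), matrix(0, 3, 3),
               tolerance = 1e-12)
})

test_that("Veronda-Westmann term matches its closed form", {
  # isochoric diagonal stretch; fibers along the compressed axis contribute
  # nothing, volumetric term is zero, so energy reduces to the ground
  # substance formula evaluated at the state's invariants
  mp <- material_params(C1 = 1, C2 = 1, C3 = 1e-9, C4 = 1, C5 = 1e-9,
                        lambda_m = 1.05, fiber_dir = c(0, 0, 1))
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  st <- deformation_state(F, fiber_dir = c(0, 0, 1))
  closed <- (exp(st$I1_tilde - 3) - 1) - 0.5 * (st$I2_tilde - 3)
  expect_equal(strain_energy(st, mp), closed, tolerance = 1e-9)
  # and the printed-value check of the same formula at I1 = 3.1, I2 = 3.05
  expect_equal((exp(0.1) - 1) - 0.5 * 0.05, 0.0802, tolerance = 1e-3)
})

test_that("fibers store no energy and carry no stress in compression", {
  mp1 <- average_material(fiber_dir = c(1, 0, 0))
  mp2 <- material_params(C1 = 0.78, C2 = 1.20, C3 = 4.3, C4 = 20, C5 = 500,
                         lambda_m = 1.1, fiber_dir = c(1, 0, 0))
  lam <- 1.3  # fiber axis x is compressed: lambda_tilde = 1/sqrt(lam) < 1
  F <- diag(c(1 / sqrt(lam), lam, 1 / sqrt(lam)))
  st <- deformation_state(F, fiber_dir = c(1, 0, 0))
  expect_lt(st$lambda_tilde, 1)
  expect_equal(strain_energy(st, mp1), strain_energy(st, mp2),
               tolerance = 1e-12)
  expect_equal(cauchy_stress_undamaged(st, mp1),
               cauchy_stress_undamaged(st, mp2), tolerance = 1e-12)
})

test_that("fiber energy matches an independent quadrature oracle", {
  mp <- average_material()
  for (lam in c(1.01, 1.03, 1.048, 1.1, 1.2)) {
    expect_equal(meniscusCDM:::cpp_fiber_energy(lam, c(mp$C1, mp$C2, mp$C3, mp$C4, mp$C5,
                                         mp$C6, mp$lambda_m, mp$K)),
                 fiber_energy_oracle(lam, mp), tolerance = 1e-9)
  }
})

test_that("C6 makes the two fiber branches agree at the transition stretch", {
  # printed fitted averages
  C6 <- compute_C6(0.43, 40.83, 119.63, 1.048)
  expect_equal(C6, -122.7, tolerance = 1e-3)
  toe <- 0.43 * (exp(40.83 * (1.048 - 1)) - 1)
  lin <- 119.63 * 1.048 + C6
  expect_equal(toe, lin, tolerance = 1e-12)
  # degenerate limit: no linear modulus and lambda_m -> 1+
  expect_equal(compute_C6(5, 12, 0, 1 + 1e-9), 0, tolerance = 1e-6)
  # property: branch values equal at lambda_m for arbitrary parameters
  set.seed(42)
  for (i in 1:20) {
    C3 <- runif(1, 0.01, 2); C4 <- runif(1, 5, 60)
    C5 <- runif(1, 1, 300); lm <- runif(1, 1.01, 1.2)
    C6 <- compute_C6(C3, C4, C5, lm)
    expect_equal(C3 * (exp(C4 * (lm - 1)) - 1), C5 * lm + C6,
                 tolerance = 1e-10 * max(1, C5))
  }
})

test_that("analytic stress agrees with numeric energy differentiation", {
  mp <- average_material(fiber_dir = c(0.36, 0.48, 0.8))
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    F <- random_state()
    s_an <- cauchy_stress_undamaged(deformation_state(F), mp)
    s_nu <- numeric_cauchy_stress(F, mp)
    worst <- max(worst, max(abs(s_an - s_nu)) / max(abs(s_nu), 1e-10))
  }
  expect_lt(worst, 1e-3)
})

test_that("stress is objective under superposed rotations", {
  mp <- average_material(fiber_dir = c(0, 1, 0))
  set.seed(11)
  for (i in 1:20) {
    F <- random_state()
    Q <- random_rotation()
    s1 <- cauchy_stress_undamaged(deformation_state(Q %*% F), mp)
    s2 <- Q %*% cauchy_stress_undamaged(deformation_state(F), mp) %*% t(Q)
    expect_lt(max(abs(s1 - s2)), 1e-10 * max(1, max(abs(s2))))
  }
})

test_that("fiber stress is continuous across the transition stretch", {
  mp <- average_material()
  pv <- c(mp$C1, mp$C2, mp$C3, mp$C4, mp$C5, mp$C6, mp$lambda_m, mp$K)
  lo <- meniscusCDM:::cpp_fiber_g(mp$lambda_m * (1 - 1e-12), pv)
  hi <- meniscusCDM:::cpp_fiber_g(mp$lambda_m * (1 + 1e-12), pv)
  expect_lt(abs(hi - lo), 1e-10 * mp$C5)
})

test_that("non-positive volume ratios are rejected", {
  expect_error(deformation_state(diag(c(-1, 1, 1))), "determinant")
  expect_error(deformation_state(matrix(0, 3, 3)), "determinant")
})

test_that("purely volumetric response has the closed form K ln(J)/J I", {
  mp <- material_params(C1 = 1e-12, C2 = 1, C3 = 1e-12, C4 = 1, C5 = 1e-12,
                        lambda_m = 1.05, K = 1000)
  F <- diag(c(1.03, 0.99, 1.05))
  st <- deformation_state(F)
  J <- det(F)
  expect_equal(cauchy_stress_undamaged(st, mp),
               diag(3) * 1000 * log(J) / J, tolerance = 1e-8)
})

test_that("damage criteria evaluate their defining formulas", {
  # von Mises of a given deviator
  sig <- diag(c(2, -1, -1))
  st <- deformation_state(diag(3))
  expect_equal(damage_criterion(st, sig, "von_mises"), 3, tolerance = 1e-12)
  # hydrostatic stress has zero von Mises
  expect_equal(damage_criterion(st, diag(3) * 5, "von_mises"), 0,
               tolerance = 1e-12)
  # max normal strain = largest principal Lagrange strain
  E <- diag(c(0.10, -0.02, -0.03))
  F <- diag(sqrt(2 * diag(E) + 1))
  expect_equal(damage_criterion(deformation_state(F),
                                which = "max_normal_strain"),
               0.10, tolerance = 1e-12)
})

test_that("von Mises reduces to first principal stress in uniaxial tension", {
  mp <- average_material()
  grid <- seq(1, 1.12, length.out = 25)
  sol <- simulate_uniaxial(mp, NULL, "longitudinal", grid)
  for (i in c(10, 18, 25)) {
    F <- diag(c(sol$lambda_x[i], sol$stretch[i], sol$lambda_z[i]))
    st <- deformation_state(F)
    sig <- cauchy_stress_undamaged(st, mp)
    expect_lt(max(abs(sig[1, 1]), abs(sig[3, 3])), 1e-6 * abs(sig[2, 2]))
    s1 <- max(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(damage_criterion(st, sig, "von_mises"), s1,
                 tolerance = 1e-4)
  }
})

test_that("damage CDF has the quintic smoothstep properties", {
  dp <- damage_params("von_mises", mu_min = 2, mu_max = 6, D_max = 0.58)
  expect_identical(damage_cdf(2, dp), 0)
  expect_identical(damage_cdf(0.5, dp), 0)
  expect_identical(damage_cdf(6, dp), 0.58)
  expect_identical(damage_cdf(100, dp), 0.58)
  expect_equal(damage_cdf(4, dp), 0.5 * 0.58, tolerance = 1e-12)
  xs <- seq(1.9, 6.1, length.out = 400)
  D <- damage_cdf(xs, dp)
  expect_true(all(diff(D) >= -1e-15))                       # nondecreasing
  expect_lt(max(abs(diff(D)[c(1, 399)])) / diff(xs)[1], 1e-3)  # flat ends
  h <- 1e-6
  expect_lt(abs(damage_cdf(2 + h, dp) - damage_cdf(2, dp)) / h, 1e-8)
  expect_lt(abs(damage_cdf(6, dp) - damage_cdf(6 - h, dp)) / h, 1e-8)
})

test_that("damaged stress scales linearly and rejects total failure", {
  sig <- diag(c(4, 0, 0))
  expect_identical(apply_damage(sig, 0), sig)
  expect_equal(apply_damage(sig, 0.5), diag(c(2, 0, 0)))
  expect_equal(apply_damage(sig, 0.58), 0.42 * sig, tolerance = 1e-12)
  expect_error(apply_damage(sig, 1), "total failure")
  expect_error(apply_damage(sig, 1.2), "total failure")
})

test_that("damage state follows the history maximum and never heals", {
  dp <- damage_params("von_mises", mu_min = 1, mu_max = 3, D_max = 0.6)
  st <- damage_state()
  # loading ramp, unload, reload: oracle is a running maximum scan
  path <- c(seq(0.5, 2.5, length.out = 20), seq(2.5, 0.5, length.out = 10),
            seq(0.5, 2.0, length.out = 10))
  trace <- numeric(length(path))
  for (i in seq_along(path)) {
    st <- update_damage_state(st, path[i], dp)
    trace[i] <- st$D
    expect_equal(st$D, damage_cdf(max(path[1:i]), dp), tolerance = 1e-14)
  }
  expect_true(all(diff(trace) >= 0))
  # unloading leaves the state untouched
  st2 <- update_damage_state(st, 0.1, dp)
  expect_identical(st2$xi_max, st$xi_max)
  expect_identical(st2$D, st$D)
})

test_that("parameter validation rejects inadmissible inputs", {
  expect_error(material_params(C1 = -1, C2 = 1, C3 = 1, C4 = 1, C5 = 1,
                               lambda_m = 1.05), "positive")
  expect_error(material_params(C1 = 1, C2 = 1, C3 = 1, C4 = 1, C5 = 1,
                               lambda_m = 0.9), "lambda_m")
  expect_error(damage_params("von_mises", mu_min = 3, mu_max = 2,
                             D_max = 0.5), "exceed")
  expect_error(damage_params("von_mises", mu_min = 1, mu_max = 2, D_max = 1),
               "D_max")
})
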