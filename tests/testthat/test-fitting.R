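make_curve <- function(stretch, force, orientation = "longitudinal") {
  tensile_curve(stretch, force, orientation, gauge_length = 6.4, area = 1.2)
}

test_that("yield detection finds the maximum-slope sample", {
  # piecewise-linear toe (slope 1) / stiff (slope 5) / softening (slope -1)
  e <- seq(0, 0.3, length.out = 61)
  f <- ifelse(e <= 0.1, e,
              ifelse(e <= 0.2, 0.1 + 5 * (e - 0.1), 0.6 - (e - 0.2)))
  cv <- make_curve(1 + e, f)
  y <- detect_yield(cv, smoothing_window_frac = 0.08)
  # oracle: exhaustive central-difference slope scan
  sl <- diff(f) / diff(e)
  stiff <- range(which(sl > 4))
  expect_gte(y$index, stiff[1])
  expect_lte(y$index, stiff[2] + 1)
  expect_false(y$degenerate)
})

test_that("a straight line is degenerate and resolves to the earliest sample", {
  cv <- make_curve(seq(1, 1.3, length.out = 31),
                   seq(0, 3, length.out = 31))
  y <- detect_yield(cv)
  expect_true(y$degenerate)
  expect_lte(y$index, 3)
})

test_that("sigmoid curves yield at their inflection", {
  e <- seq(0, 0.3, length.out = 121)
  c0 <- 0.15; k <- 40
  f <- 1 / (1 + exp(-k * (e - c0))) - 1 / (1 + exp(k * c0))
  cv <- make_curve(1 + e, f)
  y <- detect_yield(cv, smoothing_window_frac = 0.1)
  expect_equal(y$stretch - 1, c0, tolerance = 0.015)  # analytic inflection
})

test_that("yield detection is invariant to force rescaling", {
  tr <- synthetic_truth("longitudinal", "von_mises")
  cv <- generate_curve_model_based(tr$params, tr$dp,
                                   generator_spec("longitudinal",
                                                  seed = 5))$curve
  cv10 <- cv; cv10$force <- cv10$force * 10
  expect_identical(detect_yield(cv)$index, detect_yield(cv10)$index)
  expect_error(detect_yield(cv[1:5, ]), "7 samples")
})

test_that("fit quality metrics match closed forms and a two-line oracle", {
  tr <- synthetic_truth("longitudinal", "von_mises")
  cv <- generate_curve_model_based(tr$params, tr$dp,
                                   generator_spec("longitudinal", seed = 8,
                                                  noise_sd = 0))$curve
  q <- fit_quality(cv, cv)
  expect_equal(q$nrmse, 0, tolerance = 1e-10)
  expect_equal(q$r2, 1, tolerance = 1e-12)
  # constant offset: NRMSE = 100 c / mean force (mean taken on the common
  # resampling grid, as the metric defines it)
  cvc <- cv; cvc$force <- cv$force + 0.2
  gridc <- seq(1, max(cv$stretch), length.out = 200)
  expect_equal(fit_quality(cvc, cv)$nrmse,
               100 * 0.2 / mean(approx(cv$stretch, cv$force, gridc)$y),
               tolerance = 1e-9)
  # scaling: R^2 from the brute-force definition on the same grid
  cvs <- cv; cvs$force <- 1.1 * cv$force
  grid <- seq(1, max(cv$stretch), length.out = 200)
  fm <- approx(cvs$stretch, cvs$force, grid)$y
  ft <- approx(cv$stretch, cv$force, grid)$y
  expect_equal(fit_quality(cvs, cv)$r2,
               1 - sum((ft - fm)^2) / sum((ft - mean(ft))^2),
               tolerance = 1e-10)
  zero <- make_curve(c(1, 1.1, 1.2), c(0, 1e-18, -1e-18))
  expect_error(fit_quality(zero, zero), "zero mean")
})

test_that("self-consistent elastic fit recovers the generating parameters", {
  trT <- synthetic_truth("transverse", "von_mises")
  trL <- synthetic_truth("longitudinal", "von_mises")
  cT <- generate_curve_model_based(trT$params, trT$dp,
                                   generator_spec("transverse", seed = 1,
                                                  noise_sd = 0))$curve
  cL <- generate_curve_model_based(trL$params, trL$dp,
                                   generator_spec("longitudinal", seed = 1,
                                                  noise_sd = 0))$curve
  init <- list(C1 = trT$params$C1, C2 = trT$params$C2, C3 = trL$params$C3,
               C4 = trL$params$C4, C5 = trL$params$C5,
               lambda_m = trL$params$lambda_m)
  fit <- fit_elastic(cT, cL, init = init)
  expect_equal(fit$params$C1, trT$params$C1, tolerance = 0.02)
  expect_equal(fit$params$C5, trL$params$C5, tolerance = 0.02)
  expect_gt(fit$transverse_quality$r2, 0.9999)
  expect_gt(fit$longitudinal_quality$r2, 0.999)
})

test_that("noisy transverse curves recover C1 within 10 percent", {
  trT <- synthetic_truth("transverse", "von_mises")
  trL <- synthetic_truth("longitudinal", "von_mises")
  cT <- generate_curve_model_based(trT$params, trT$dp,
                                   generator_spec("transverse",
                                                  seed = 21))$curve
  cL <- generate_curve_model_based(trL$params, trL$dp,
                                   generator_spec("longitudinal",
                                                  seed = 22))$curve
  init <- list(C1 = trT$params$C1 * 1.5, C2 = 1, C3 = trL$params$C3 * 0.7,
               C4 = 30, C5 = trL$params$C5 * 1.4, lambda_m = 1.05)
  fit <- fit_elastic(cT, cL, init = init)
  expect_lt(abs(fit$params$C1 - trT$params$C1) / trT$params$C1, 0.1)
})

test_that("bound expansion frees a pinned parameter", {
  trT <- synthetic_truth("transverse", "von_mises")
  trL <- synthetic_truth("longitudinal", "von_mises")
  cT <- generate_curve_model_based(trT$params, trT$dp,
                                   generator_spec("transverse", seed = 2,
                                                  noise_sd = 0))$curve
  cL <- generate_curve_model_based(trL$params, trL$dp,
                                   generator_spec("longitudinal", seed = 2,
                                                  noise_sd = 0))$curve
  # C1 guess and bounds set far below the truth: the first solve must pin at
  # the upper bound and trigger the 30% expansion loop
  init <- list(C1 = trT$params$C1 / 4, C2 = trT$params$C2, C3 = trL$params$C3,
               C4 = trL$params$C4, C5 = trL$params$C5,
               lambda_m = trL$params$lambda_m)
  fit <- fit_elastic(cT, cL, init = init,
                     upper = list(C1 = trT$params$C1 / 2))
  expect_gte(fit$expansions["transverse"], 1)
  expect_gt(fit$params$C1, trT$params$C1 / 2)  # escaped the original bound
  expect_equal(fit$params$C1, trT$params$C1, tolerance = 0.05)
})

test_that("damage fit seeded at a consistent curve succeeds immediately", {
  tr <- synthetic_truth("longitudinal", "von_mises")
  cv <- generate_curve_model_based(tr$params, tr$dp,
                                   generator_spec("longitudinal", seed = 3,
                                                  noise_sd = 0))$curve
  fd <- fit_damage(cv, tr$params, "von_mises", budget = 120)
  expect_true(fd$success)
  expect_true(all(fd$flags))
  expect_lte(fd$e_stress, fd$tolerances$stress)
  expect_lte(fd$e_strain, fd$tolerances$strain)
  expect_gte(fd$post_uts_drop, fd$tolerances$drop)
})

test_that("elastic fit is stable under target resampling density", {
  trT <- synthetic_truth("transverse", "von_mises")
  trL <- synthetic_truth("longitudinal", "von_mises")
  fits <- lapply(c(150, 300), function(n) {
    cT <- generate_curve_model_based(trT$params, trT$dp,
            generator_spec("transverse", seed = 4, noise_sd = 0, n = n))$curve
    cL <- generate_curve_model_based(trL$params, trL$dp,
            generator_spec("longitudinal", seed = 4, noise_sd = 0, n = n))$curve
    init <- list(C1 = trT$params$C1 * 1.2, C2 = 1, C3 = trL$params$C3,
                 C4 = trL$params$C4, C5 = trL$params$C5 * 0.9,
                 lambda_m = trL$params$lambda_m)
    fit_elastic(cT, cL, init = init)$params
  })
  expect_lt(abs(fits[[1]]$C1 - fits[[2]]$C1) / fits[[2]]$C1, 0.01)
  expect_lt(abs(fits[[1]]$C5 - fits[[2]]$C5) / fits[[2]]$C5, 0.01)
})

test_that("the fitted model object exposes the standard methods", {
  trT <- synthetic_truth("transverse", "von_mises")
  trL <- synthetic_truth("longitudinal", "von_mises")
  cT <- generate_curve_model_based(trT$params, trT$dp,
                                   generator_spec("transverse", seed = 6))$curve
  cL <- generate_curve_model_based(trL$params, trL$dp,
                                   generator_spec("longitudinal", seed = 6))$curve
  fit <- cdm_fit(cT, cL, criterion = "von_mises", damage_budget = 80)
  co <- coef(fit)
  expect_true(all(c("C1", "C5", "lambda_m", "longitudinal.D_max",
                    "transverse.mu_min") %in% names(co)))
  pr <- predict(fit, "longitudinal")
  expect_equal(nrow(pr), nrow(cL))
  expect_gt(max(pr$force), 0)
  rs <- residuals(fit)
  expect_length(rs$longitudinal, nrow(cL))
  sims <- simulate(fit, nsim = 1, seed = 9)
  expect_s3_class(sims$transverse[[1]], "tensile_curve")
  expect_output(print(fit), "CDM tensile fit")
  expect_output(summary(fit), "calibration summary")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
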