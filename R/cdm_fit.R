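#' Fit the damage material to tensile curves
#'
#' The central fitting function: given one (or more) transverse and one (or
#' more) longitudinal grip-to-grip tensile curves, it runs the sequential
#' calibration — yield detection, bounded Levenberg-Marquardt fit of the
#' ground substance to the transverse data up to yield, then of the fiber
#' network to the longitudinal data up to yield (with bound expansion), then
#' a deterministic coordinate search of the damage parameters per orientation
#' against explicit success criteria — and returns a fitted model object.
#'
#' @param transverse,longitudinal [tensile_curve()] objects or lists of them.
#' @param criterion damage criterion, `"von_mises"` or `"max_normal_strain"`.
#' @param init optional named list of elastic initial guesses (`C1`, `C2`,
#'   `C3`, `C4`, `C5`, `lambda_m`). Defaults are derived from the curves:
#'   `C2 = 1`, stiffness-based guesses for `C1` and `C5`.
#' @param K bulk modulus (MPa).
#' @param damage_budget objective-evaluation budget of the damage search.
#' @param ... passed to [fit_elastic()].
#' @return An object of class `cdm_fit` with components `elastic`
#'   (see [fit_elastic()]), `damage` (per-orientation [fit_damage()] results),
#'   `params`, `criterion`, `curves`, and `quality` (per-orientation NRMSE
#'   and R-squared over the full curves).
#' @seealso [predict.cdm_fit()], [plot.cdm_fit()], [simulate.cdm_fit()]
#' @export
cdm_fit <- function(transverse, longitudinal,
                    criterion = c("von_mises", "max_normal_strain"),
                    init = NULL, K = 1000, damage_budget = 300, ...) {
  criterion <- match.arg(criterion)
  tc <- if (inherits(transverse, "tensile_curve")) list(transverse) else transverse
  lc <- if (inherits(longitudinal, "tensile_curve")) list(longitudinal) else longitudinal

  if (is.null(init)) init <- list()
  if (is.null(init$C2)) init$C2 <- 1
  if (is.null(init$C1)) {
    # secant stiffness of the transverse data at mid-curve -> modulus scale
    cv <- tc[[1]]
    mid <- max(3, round(nrow(cv) / 2))
    E_sec <- (cv$force[mid] / attr(cv, "area")) / (cv$stretch[mid] - 1)
    init$C1 <- max(E_sec / 6, 1e-4)
  }
  if (is.null(init$C5)) {
    cv <- lc[[1]]
    y <- detect_yield(cv)
    init$C5 <- max(y$slope / attr(cv, "area"), 1e-3)
  }
  if (is.null(init$C3)) init$C3 <- init$C5 / 150
  if (is.null(init$C4)) init$C4 <- 30
  if (is.null(init$lambda_m)) init$lambda_m <- 1.05

  elastic <- fit_elastic(tc, lc, init = init, K = K, ...)
  mp <- elastic$params

  dmg <- list(
    transverse = fit_damage(tc[[1]], mp, criterion, budget = damage_budget),
    longitudinal = fit_damage(lc[[1]], mp, criterion, budget = damage_budget))

  quality <- lapply(list(transverse = tc[[1]], longitudinal = lc[[1]]),
                    function(cv) {
    o <- attr(cv, "orientation")
    f <- model_force(mp, dmg[[o]]$dp, cv)
    ok <- is.finite(f)
    fit_quality(data.frame(stretch = cv$stretch[ok], force = f[ok]), cv)
  })

  out <- list(elastic = elastic, damage = dmg, params = mp,
              criterion = criterion,
              curves = list(transverse = tc, longitudinal = lc),
              quality = quality, K = K)
  class(out) <- "cdm_fit"
  out
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf("CDM tensile fit (%s damage criterion)\n", x$criterion))
  p <- x$params
  cat(sprintf("  elastic: C1 = %.4g, C2 = %.4g, C3 = %.4g, C4 = %.4g, C5 = %.4g, lambda_m = %.4g\n",
              p$C1, p$C2, p$C3, p$C4, p$C5, p$lambda_m))
  for (o in c("longitudinal", "transverse")) {
    d <- x$damage[[o]]
    cat(sprintf("  %s damage: mu_min = %.4g, mu_max = %.4g, D_max = %.3g [%s]\n",
                o, d$dp$mu_min, d$dp$mu_max, d$dp$D_max,
                if (d$success) "fit criteria met" else "fit criteria NOT met"))
  }
  cat(sprintf("  quality: longitudinal NRMSE %.2f%% (R2 %.4f), transverse NRMSE %.2f%% (R2 %.4f)\n",
              x$quality$longitudinal$nrmse, x$quality$longitudinal$r2,
              x$quality$transverse$nrmse, x$quality$transverse$r2))
  invisible(x)
}

#' @export
summary.cdm_fit <- function(object, ...) {
  x <- object
  cat("Sequential CDM calibration summary\n")
  cat("==================================\n")
  print(x$params)
  for (o in c("longitudinal", "transverse")) {
    d <- x$damage[[o]]
    cat(sprintf("\n%s damage fit (%s):\n", o, x$criterion))
    print(d$dp)
    cat(sprintf("  ultimate-stress error %.4g MPa (tol %.3g), ultimate-strain error %.4g (tol %.3g)\n",
                d$e_stress, d$tolerances$stress, d$e_strain, d$tolerances$strain))
    cat(sprintf("  post-UTS drop %.3g (required >= %.3g); %d evaluations; success: %s\n",
                d$post_uts_drop, d$tolerances$drop, d$evaluations, d$success))
  }
  cat(sprintf("\nbound expansions: transverse %d, longitudinal %d\n",
              x$elastic$expansions["transverse"],
              x$elastic$expansions["longitudinal"]))
  cat(sprintf("overall quality: longitudinal NRMSE %.2f%% R2 %.4f | transverse NRMSE %.2f%% R2 %.4f\n",
              x$quality$longitudinal$nrmse, x$quality$longitudinal$r2,
              x$quality$transverse$nrmse, x$quality$transverse$r2))
  invisible(x)
}

#' @export
coef.cdm_fit <- function(object, ...) {
  p <- object$params
  c(C1 = p$C1, C2 = p$C2, C3 = p$C3, C4 = p$C4, C5 = p$C5, C6 = p$C6,
    lambda_m = p$lambda_m, K = p$K,
    longitudinal.mu_min = object$damage$longitudinal$dp$mu_min,
    longitudinal.mu_max = object$damage$longitudinal$dp$mu_max,
    longitudinal.D_max = object$damage$longitudinal$dp$D_max,
    transverse.mu_min = object$damage$transverse$dp$mu_min,
    transverse.mu_max = object$damage$transverse$dp$mu_max,
    transverse.D_max = object$damage$transverse$dp$D_max)
}

#' Predict the model force-stretch response
#'
#' @param object a [cdm_fit()].
#' @param orientation which loading orientation to predict.
#' @param stretch stretch grid (default: the grid of the fitted curve).
#' @param damage include the fitted damage law (TRUE) or predict the purely
#'   elastic response (FALSE).
#' @param ... unused.
#' @return A data frame with `stretch` and `force` (N, full-coupon).
#' @export
predict.cdm_fit <- function(object, orientation = c("longitudinal",
                                                    "transverse"),
                            stretch = NULL, damage = TRUE, ...) {
  orientation <- match.arg(orientation)
  cv <- object$curves[[orientation]][[1]]
  if (is.null(stretch)) stretch <- cv$stretch
  if (stretch[1] > 1) stretch <- c(1, stretch)
  dp <- if (damage) object$damage[[orientation]]$dp else NULL
  sol <- simulate_uniaxial(object$params, dp, orientation, stretch)
  data.frame(stretch = sol$stretch,
             force = sol$nominal_axial * attr(cv, "area"))
}

#' @export
residuals.cdm_fit <- function(object, ...) {
  out <- lapply(c(transverse = "transverse", longitudinal = "longitudinal"),
                function(o) {
    cv <- object$curves[[o]][[1]]
    f <- model_force(object$params, object$damage[[o]]$dp, cv)
    f - cv$force
  })
  out
}

#' Plot data and fitted model curves
#'
#' @param x a [cdm_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.cdm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (o in c("longitudinal", "transverse")) {
    cv <- x$curves[[o]][[1]]
    pr <- predict(x, o)
    graphics::plot(cv$stretch, cv$force, pch = 16, cex = 0.5,
                   col = "grey40", xlab = "grip-to-grip stretch",
                   ylab = "force (N)", main = o, ...)
    graphics::lines(pr$stretch, pr$force, col = "firebrick", lwd = 2)
    graphics::legend("topleft", bty = "n", lwd = c(NA, 2), pch = c(16, NA),
                     col = c("grey40", "firebrick"),
                     legend = c("data", "model"))
  }
  invisible(x)
}

#' Simulate noisy curves from a fitted model
#'
#' @param object a [cdm_fit()].
#' @param nsim number of curves per orientation.
#' @param seed RNG seed.
#' @param noise_sd force noise standard deviation (N); default 1% of each
#'   orientation's fitted ultimate force.
#' @param ... unused.
#' @return A list with `transverse` and `longitudinal` lists of
#'   [tensile_curve()]s.
#' @export
simulate.cdm_fit <- function(object, nsim = 1, seed = 1, noise_sd = NULL,
                             ...) {
  out <- lapply(c(transverse = "transverse", longitudinal = "longitudinal"),
                function(o) {
    cv <- object$curves[[o]][[1]]
    uts <- locate_uts(cv)
    sdv <- if (is.null(noise_sd)) 0.01 * uts$force else noise_sd
    lapply(seq_len(nsim), function(i) {
      sp <- generator_spec(o, uts_force = uts$force,
                           uts_stretch = uts$stretch, noise_sd = sdv,
                           n = nrow(cv), end_stretch = max(cv$stretch),
                           seed = seed + i)
      generate_curve_model_based(object$params, object$damage[[o]]$dp, sp,
                                 geometry = list(
                                   gauge_length = attr(cv, "gauge_length"),
                                   area = attr(cv, "area")))$curve
    })
  })
  out
}
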