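#' Inter-method agreement analysis of paired RULA scores
#'
#' The package's central estimator: given per-participant RULA scores from
#' two acquisition methods (typically a continuous time-weighted IMU
#' aggregate and an integer pose-snapshot score), computes, for the
#' overall score and each body-region sub-score family:
#' \itemize{
#'   \item Cohen's weighted kappa with 95\% CI and p-value
#'     ([weighted_kappa()]), on scores rounded half-up to integer levels;
#'   \item Bland-Altman mean difference, SD and limits of agreement on
#'     the continuous scores ([bland_altman()]);
#'   \item Mann-Whitney U with rank-biserial effect size
#'     ([mann_whitney_rank_biserial()]);
#'   \item a Shapiro-Wilk normality screen of the paired differences;
#'   \item Bonferroni-adjusted p-values across the tested families.
#' }
#' Post hoc power of the two-tailed point-biserial correlation test at
#' `power_effect_size` and the study's n is attached for reference.
#'
#' @param x,y Data.frames of scores from method 1 (`x`) and method 2
#'   (`y`), same participants in the same order; columns are score
#'   families (any of `overall`, `upper_arm`, `lower_arm`, `wrist`,
#'   `neck`, `trunk`).  Numeric vectors are accepted as a single
#'   `overall` family.
#' @param method_names Length-2 character, labels for `x` and `y`.
#' @param weights Kappa weight scheme, `"linear"` (default) or
#'   `"quadratic"`.
#' @param bonferroni_m Family size for the Bonferroni correction;
#'   defaults to the number of score families tested.
#' @param alpha Significance level.  Default 0.05.
#' @param power_effect_size Effect size at which post hoc power is
#'   evaluated.  Default 0.45.
#' @return Object of class `rula_agreement` with per-family statistics;
#'   see [print.rula_agreement()], [summary.rula_agreement()],
#'   [plot.rula_agreement()], [coef.rula_agreement()].
#' @export
#' @examples
#' set.seed(1)
#' imu <- data.frame(overall = sample(3:7, 45, TRUE))
#' pose <- data.frame(overall = pmin(7, pmax(1, imu$overall +
#'                    sample(-1:1, 45, TRUE))))
#' fit <- rula_agreement(imu, pose)
#' coef(fit)
rula_agreement <- function(x, y, method_names = c("method1", "method2"),
                           weights = c("linear", "quadratic"),
                           bonferroni_m = NULL, alpha = 0.05,
                           power_effect_size = 0.45) {
  weights <- match.arg(weights)
  if (is.numeric(x)) x <- data.frame(overall = x)
  if (is.numeric(y)) y <- data.frame(overall = y)
  x <- as.data.frame(x); y <- as.data.frame(y)
  fams <- intersect(names(.rula_family_levels), intersect(names(x), names(y)))
  if (!length(fams))
    stop(input_error("no common score families between x and y"))
  if (nrow(x) != nrow(y) || nrow(x) < 2L)
    stop(input_error("x and y must have the same number of rows (>= 2)"))
  if (any(is.na(x[fams])) || any(is.na(y[fams])))
    stop(input_error("paired scores must not contain missing values"))
  m <- if (is.null(bonferroni_m)) length(fams) else bonferroni_m
  n <- nrow(x)

  families <- lapply(fams, function(f) {
    k <- .rula_family_levels[[f]]
    xi <- .round_levels(x[[f]], k)
    yi <- .round_levels(y[[f]], k)
    kap <- tryCatch(weighted_kappa(xi, yi, k_levels = k, weights = weights),
                    rulagree_degenerate_error = function(e) NULL)
    ba <- bland_altman(x[[f]], y[[f]])
    mw <- mann_whitney_rank_biserial(x[[f]], y[[f]])
    sw <- tryCatch(normality_check(x[[f]] - y[[f]]),
                   error = function(e) list(W = NA_real_,
                                            p_value = NA_real_))
    list(family = f, k_levels = k, kappa = kap, bland_altman = ba,
         mannwhitney = mw, shapiro = sw)
  })
  names(families) <- fams

  kp <- vapply(families, function(f)
    if (is.null(f$kappa)) NA_real_ else f$kappa$p_value, numeric(1))
  mp <- vapply(families, function(f) f$mannwhitney$p_value, numeric(1))
  kp_adj <- stats::setNames(ifelse(is.na(kp), NA_real_, pmin(1, kp * m)),
                            fams)
  mp_adj <- stats::setNames(pmin(1, mp * m), fams)
  for (f in fams) {
    families[[f]]$kappa_p_bonferroni <- kp_adj[[f]]
    families[[f]]$mannwhitney_p_bonferroni <- mp_adj[[f]]
  }

  structure(list(families = families, n = n,
                 method_names = method_names, weights = weights,
                 bonferroni_m = m, alpha = alpha,
                 power = posthoc_power_point_biserial(power_effect_size,
                                                      alpha, n),
                 power_effect_size = power_effect_size,
                 data = list(x = x[fams], y = y[fams])),
            class = "rula_agreement")
}

.rula_family_levels <- c(overall = 7L, upper_arm = 6L, lower_arm = 3L,
                         wrist = 4L, neck = 6L, trunk = 6L)

# round half-up to an integer level, clamped to 1..k
.round_levels <- function(v, k) {
  pmin(k, pmax(1L, as.integer(floor(v + 0.5))))
}

#' @export
print.rula_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("RULA inter-method agreement (%s vs %s), n = %d\n",
              x$method_names[1], x$method_names[2], x$n))
  cat(sprintf("weighted kappa (%s weights), Bonferroni m = %d\n\n",
              x$weights, x$bonferroni_m))
  print(coef(x), digits = digits)
  cat(sprintf(
    "\npost hoc power at r = %.2f (two-tailed, alpha = %.2f): %.1f%%\n",
    x$power_effect_size, x$alpha, 100 * x$power))
  invisible(x)
}

#' Per-family agreement coefficients
#'
#' @param object A [rula_agreement()] fit.
#' @param ... Unused.
#' @return Data.frame with one row per score family: kappa, its 95\% CI
#'   and (adjusted) p-value, Bland-Altman mean difference and limits of
#'   agreement, Mann-Whitney U, p and rank-biserial correlation.
#' @export
coef.rula_agreement <- function(object, ...) {
  do.call(rbind, lapply(object$families, function(f) {
    kap <- f$kappa
    data.frame(family = f$family,
               kappa = if (is.null(kap)) NA_real_ else kap$kappa,
               kappa_lo = if (is.null(kap)) NA_real_ else kap$ci[1],
               kappa_hi = if (is.null(kap)) NA_real_ else kap$ci[2],
               kappa_p = if (is.null(kap)) NA_real_ else kap$p_value,
               kappa_pB = f$kappa_p_bonferroni,
               mean_diff = f$bland_altman$mean_diff,
               loa_lo = f$bland_altman$loa[1],
               loa_hi = f$bland_altman$loa[2],
               U = f$mannwhitney$U,
               mw_p = f$mannwhitney$p_value,
               mw_pB = f$mannwhitney_p_bonferroni,
               rank_biserial = f$mannwhitney$rank_biserial,
               shapiro_p = f$shapiro$p_value,
               row.names = NULL)
  }))
}

#' @export
summary.rula_agreement <- function(object, ...) {
  out <- list(coefficients = coef(object), n = object$n,
              weights = object$weights, power = object$power,
              alpha = object$alpha,
              method_names = object$method_names)
  class(out) <- "summary.rula_agreement"
  out
}

#' @export
print.summary.rula_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement summary (%s vs %s), n = %d, %s kappa weights\n",
              x$method_names[1], x$method_names[2], x$n, x$weights))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' Bland-Altman plot of a score family
#'
#' Per-pair mean vs difference with the mean-difference line (solid) and
#' the 1.96-SD limits of agreement (dotted).
#'
#' @param x A [rula_agreement()] fit.
#' @param family Score family to plot.  Default `"overall"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rula_agreement <- function(x, family = "overall", ...) {
  f <- x$families[[family]]
  if (is.null(f))
    stop(input_error(paste0("no such score family: ", family)))
  ba <- f$bland_altman
  graphics::plot(ba$points$mean, ba$points$diff,
                 xlab = paste("mean of", x$method_names[1], "and",
                              x$method_names[2]),
                 ylab = paste("difference (", x$method_names[1], "-",
                              x$method_names[2], ")"),
                 main = paste("Bland-Altman:", family), pch = 19, ...)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = ba$loa, lty = 3)
  invisible(x)
}
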