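#' Cohen's weighted kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement for paired ordinal ratings on levels
#' `1..k_levels`, with partial credit for near-misses:
#' \deqn{\kappa_w = (P_{o,w} - P_{e,w}) / (1 - P_{e,w})}
#' using agreement weights \eqn{w_{ij} = 1 - |i-j|/(k-1)} (linear) or
#' \eqn{w_{ij} = 1 - ((i-j)/(k-1))^2} (quadratic).  The confidence
#' interval uses the Fleiss-Cohen-Everitt large-sample variance of
#' weighted kappa; the p-value tests \eqn{\kappa = 0} with the
#' corresponding null variance (two-sided normal test).
#'
#' @param x,y Integer ratings in `1..k_levels`, paired and equal length
#'   (n >= 2).
#' @param k_levels Number of ordinal levels (default: largest observed).
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param conf_level Confidence level for the interval.  Default 0.95.
#' @return List: `kappa`, `ci` (lower, upper), `se`, `p_value`, `po`,
#'   `pe`, `weights`, `n`.
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3, 1), c(1, 2, 3, 2), k_levels = 3)$kappa  # 0.714
weighted_kappa <- function(x, y, k_levels = max(c(x, y)),
                           weights = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  n <- length(x)
  if (length(y) != n || n < 2L)
    stop(input_error("x and y must be paired vectors of equal length >= 2"))
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x != round(x)) || any(y != round(y)) ||
      any(x < 1) || any(y < 1) || any(x > k_levels) || any(y > k_levels))
    stop(input_error("ratings must be integers in 1..k_levels"))
  k <- as.integer(k_levels)
  if (k < 2L) stop(input_error("k_levels must be >= 2"))

  w <- .kappa_weights(k, weights)
  tab <- table(factor(x, levels = 1:k), factor(y, levels = 1:k))
  p <- tab / n
  pi. <- rowSums(p)
  p.j <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi., p.j))
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    stop(errorCondition(
      "weighted kappa undefined: chance agreement equals 1 (degenerate marginals)",
      class = c("rulagree_degenerate_error", "error", "condition")))
  kap <- (po - pe) / (1 - pe)

  # Fleiss, Cohen & Everitt asymptotic variances
  wi. <- as.vector(w %*% p.j)        # row-weighted means
  w.j <- as.vector(pi. %*% w)        # column-weighted means
  wsum <- outer(wi., w.j, "+")
  var_k <- (sum(p * (w * (1 - pe) - wsum * (1 - po))^2) -
              (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  var_k <- max(var_k, 0)
  var0 <- (sum(outer(pi., p.j) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  var0 <- max(var0, 0)

  z975 <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(var_k)
  p_value <- if (var0 > 0)
    2 * stats::pnorm(-abs(kap) / sqrt(var0)) else NA_real_
  list(kappa = kap, ci = c(kap - z975 * se, kap + z975 * se), se = se,
       p_value = p_value, po = po, pe = pe, weights = weights, n = n)
}

.kappa_weights <- function(k, scheme) {
  d <- abs(outer(1:k, 1:k, "-")) / (k - 1)
  if (scheme == "linear") 1 - d else 1 - d^2
}

#' Bland-Altman limits of agreement
#'
#' Method-comparison statistics for paired measurements: elementwise
#' differences `d = x - y`, their mean and sample standard deviation, and
#' the limits of agreement `mean(d) +/- 1.96 sd(d)` expected to contain
#' ~95\% of differences under normality.  Per-pair means and differences
#' are returned for plotting.
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @return List: `mean_diff`, `sd_diff`, `loa` (lower, upper), `points`
#'   (data.frame with `mean` and `diff`), `n`.
#' @export
#' @examples
#' bland_altman(c(4, 5, 6), c(5, 5, 4))$mean_diff  # 0.333
bland_altman <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L)
    stop(input_error("x and y must be paired vectors of equal length >= 2"))
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(m - 1.96 * s, m + 1.96 * s),
       points = data.frame(mean = (x + y) / 2, diff = d), n = n)
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sample rank test with midrank handling of ties.  `U` counts the
#' pairs in which `x` exceeds `y` (ties count one half), so the
#' rank-biserial correlation
#' \deqn{r_{rb} = 2U/(n_1 n_2) - 1 = (favorable - unfavorable)/(n_1 n_2)}
#' is +1 when every `x` exceeds every `y` and -1 in the reverse case
#' (equivalently \eqn{1 - 2U'/(n_1 n_2)} with `U'` the opposite-orientation
#' statistic).  The default p-value uses the normal approximation with the
#' tie-corrected variance (no continuity correction, comparable to common
#' statistics packages); `method = "exact"` uses the exact null
#' distribution (tie-free data, n1*n2 <= 400).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param method `"normal"` (default) or `"exact"`.
#' @return List: `U`, `p_value`, `rank_biserial`, `n1`, `n2`, `method`.
#' @export
mann_whitney_rank_biserial <- function(x, y, method = c("normal", "exact")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop(input_error("both samples must be non-empty"))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop(input_error("samples must be finite numeric"))
  all_v <- c(x, y)
  N <- n1 + n2
  r <- rank(all_v)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs with x > y (+ ties/2)
  r_rb <- 2 * U / (n1 * n2) - 1

  ties <- table(all_v)
  if (method == "exact") {
    if (any(ties > 1))
      stop(input_error("exact method requires tie-free data"))
    if (n1 * n2 > 400)
      stop(input_error("exact method limited to n1*n2 <= 400"))
    lo <- min(U, n1 * n2 - U)
    p <- min(1, 2 * stats::pwilcox(lo, n1, n2))
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p_value = p, rank_biserial = r_rb, n1 = n1, n2 = n2,
       method = method)
}

#' Bonferroni correction for multiple comparisons
#'
#' `p_adj = min(1, p * m)` for a family of `m` tests (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Family size (>= 1; default the number of p-values).
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni(0.001, m = 6)  # 0.006
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop(input_error("p-values must lie in [0, 1]"))
  if (m < 1 || m < length(p_values))
    stop(input_error("m must be >= max(1, length(p_values))"))
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over [stats::shapiro.test()] (3 <= n <= 5000).  A
#' zero-variance sample is rejected with an error, matching the reference
#' implementation's behaviour on degenerate input.
#'
#' @param values Numeric sample.
#' @return List with `W` and `p_value`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop(input_error("Shapiro-Wilk requires 3 <= n <= 5000"))
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Post hoc power for a point-biserial correlation
#'
#' Power of the two-tailed t-test of a (point-biserial) correlation
#' coefficient at true effect size `r`, significance level `alpha` and
#' total sample size `n`.  The default model uses the noncentral-t
#' distribution with noncentrality \eqn{\delta = r\sqrt{n}/\sqrt{1-r^2}}
#' and `n - 2` degrees of freedom; `model = "fisher_z"` gives the
#' Fisher-z approximation of the bivariate-normal correlation test (a
#' slightly more conservative alternative).
#'
#' @param r True effect size, 0 < r < 1.
#' @param alpha Significance level, in (0, 1).  Default 0.05.
#' @param n Total sample size (>= 4).
#' @param tails 1 or 2 (default 2).
#' @param model `"noncentral_t"` (default) or `"fisher_z"`.
#' @return Power in (0, 1).
#' @export
#' @examples
#' posthoc_power_point_biserial(0.45, 0.05, 45)  # 0.9105
posthoc_power_point_biserial <- function(r, alpha = 0.05, n, tails = 2,
                                         model = c("noncentral_t",
                                                   "fisher_z")) {
  model <- match.arg(model)
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop(input_error("effect size r must lie in (0, 1)"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop(input_error("alpha must lie in (0, 1)"))
  if (!is.finite(n) || n < 4)
    stop(input_error("n must be >= 4"))
  if (!tails %in% c(1, 2))
    stop(input_error("tails must be 1 or 2"))
  if (model == "noncentral_t") {
    df <- n - 2
    ncp <- r * sqrt(n) / sqrt(1 - r^2)
    tcrit <- stats::qt(1 - alpha / tails, df)
    pow <- 1 - stats::pt(tcrit, df, ncp = ncp)
    if (tails == 2) pow <- pow + stats::pt(-tcrit, df, ncp = ncp)
  } else {
    if (n < 4) stop(input_error("fisher_z model needs n >= 4"))
    zr <- atanh(r) * sqrt(n - 3)
    zcrit <- stats::qnorm(1 - alpha / tails)
    pow <- stats::pnorm(zr - zcrit)
    if (tails == 2) pow <- pow + stats::pnorm(-zr - zcrit)
  }
  pow
}
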