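test_that("weighted kappa reproduces hand-computed and limiting cases", {
  # perfect agreement
  expect_equal(weighted_kappa(c(1, 2, 3, 2), c(1, 2, 3, 2),
                              k_levels = 3)$kappa, 1)
  # hand evaluation of the double-sum definition:
  # Po,w = 0.875, Pe,w = 0.5625 -> kappa = 0.714286
  k <- weighted_kappa(c(1, 2, 3, 1), c(1, 2, 3, 2), k_levels = 3,
                      weights = "linear")
  expect_equal(k$po, 0.875)
  expect_equal(k$pe, 0.5625)
  expect_equal(k$kappa, 0.714286, tolerance = 1e-6)
  expect_true(k$ci[1] <= k$kappa && k$kappa <= k$ci[2])
  # independent ratings concentrate near zero
  set.seed(31)
  x <- sample(1:7, 10000, replace = TRUE)
  y <- sample(1:7, 10000, replace = TRUE)
  expect_lt(abs(weighted_kappa(x, y, k_levels = 7)$kappa), 0.03)
  # degenerate marginals are refused, not silently returned
  expect_error(weighted_kappa(rep(2L, 5), rep(2L, 5), k_levels = 3),
               class = "rulagree_degenerate_error")
})

test_that("weighted kappa equals the brute-force double sum on random tables", {
  set.seed(32)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(6:40, 1)
    x <- sample(1:k, n, replace = TRUE)
    y <- pmin(k, pmax(1, x + sample(-1:1, n, replace = TRUE)))
    if (length(unique(c(x, y))) < 2) next
    for (scheme in c("linear", "quadratic")) {
      got <- weighted_kappa(x, y, k_levels = k, weights = scheme)$kappa
      expect_equal(got, bf_weighted_kappa(x, y, k, scheme),
                   tolerance = 1e-10)
    }
    # symmetry in the two raters
    expect_equal(weighted_kappa(x, y, k_levels = k)$kappa,
                 weighted_kappa(y, x, k_levels = k)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa confidence interval narrows with n and p-value detects agreement", {
  set.seed(33)
  make_agree <- function(n) {
    x <- sample(1:5, n, replace = TRUE)
    y <- ifelse(stats::runif(n) < 0.8, x,
                pmin(5, pmax(1, x + sample(c(-1, 1), n, replace = TRUE))))
    list(x = x, y = y)
  }
  small <- make_agree(30); big <- make_agree(3000)
  ks <- weighted_kappa(small$x, small$y, k_levels = 5)
  kb <- weighted_kappa(big$x, big$y, k_levels = 5)
  expect_lt(diff(kb$ci), diff(ks$ci))
  expect_lt(kb$p_value, 0.001)
})

test_that("Bland-Altman statistics match hand arithmetic and its invariances", {
  expect_equal(bland_altman(1:5, 1:5)$mean_diff, 0)
  expect_equal(bland_altman(1:5, 1:5)$loa, c(0, 0))
  ba <- bland_altman(c(4, 5, 6), c(5, 5, 4))
  expect_equal(ba$mean_diff, 1 / 3, tolerance = 1e-4)
  expect_equal(ba$sd_diff, 1.52753, tolerance = 1e-4)
  expect_equal(ba$loa, c(-2.6606, 3.3273), tolerance = 1e-4)
  expect_true(ba$loa[1] <= ba$mean_diff && ba$mean_diff <= ba$loa[2])
  # translation invariance and antisymmetry
  set.seed(34)
  x <- rnorm(40); y <- rnorm(40)
  b0 <- bland_altman(x, y)
  bc <- bland_altman(x + 11.5, y + 11.5)
  expect_equal(bc$mean_diff, b0$mean_diff, tolerance = 1e-12)
  expect_equal(bc$sd_diff, b0$sd_diff, tolerance = 1e-12)
  expect_equal(bc$loa, b0$loa, tolerance = 1e-12)
  expect_equal(bland_altman(y, x)$mean_diff, -b0$mean_diff)
  expect_error(bland_altman(1, 1), class = "rulagree_input_error")
})

test_that("Mann-Whitney U and rank-biserial match brute-force pair counting", {
  # complete separation
  sep <- mann_whitney_rank_biserial(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$rank_biserial, 1)
  expect_equal(mann_whitney_rank_biserial(c(1, 2), c(8, 9))$rank_biserial,
               -1)
  # identical multisets
  sym <- mann_whitney_rank_biserial(c(1, 2, 2, 5), c(2, 5, 1, 2))
  expect_equal(sym$U, 16 / 2)
  expect_equal(sym$rank_biserial, 0)
  # brute force, including ties
  set.seed(35)
  for (i in 1:50) {
    x <- sample(1:6, sample(3:10, 1), replace = TRUE)
    y <- sample(1:6, sample(3:10, 1), replace = TRUE)
    bf <- bf_rank_biserial(x, y)
    got <- mann_whitney_rank_biserial(x, y)
    expect_equal(got$U, bf$U)
    expect_equal(got$rank_biserial, bf$r_rb, tolerance = 1e-12)
  }
  expect_error(mann_whitney_rank_biserial(numeric(0), 1:3),
               class = "rulagree_input_error")
})

test_that("Mann-Whitney p-values agree with the reference implementation", {
  set.seed(36)
  x <- rnorm(18); y <- rnorm(15, 0.7)   # continuous, tie-free
  got <- mann_whitney_rank_biserial(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  ex <- mann_whitney_rank_biserial(x, y, method = "exact")
  refe <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ex$p_value, refe$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.001, m = 6), 0.006)
  expect_equal(bonferroni(0.5, m = 6), 1)
  expect_equal(bonferroni(0.123, m = 1), 0.123)
  expect_equal(bonferroni(c(0.01, 0.2), m = 4), c(0.04, 0.8))
  expect_error(bonferroni(1.2, m = 2), class = "rulagree_input_error")
})

test_that("the normality screen flags skewed but not normal samples", {
  set.seed(37)
  expect_gt(normality_check(rnorm(100))$p_value, 0.05)
  expect_lt(normality_check(rexp(100))$p_value, 0.05)
  expect_error(normality_check(rep(1, 50)))
  expect_error(normality_check(rnorm(2)), class = "rulagree_input_error")
})

test_that("post hoc power matches the noncentral-t value and a simulation oracle", {
  expect_equal(100 * posthoc_power_point_biserial(0.45, 0.05, 45),
               91.05, tolerance = 0.5)
  # limits and monotonicity
  expect_gt(posthoc_power_point_biserial(0.999, 0.05, 45), 0.9999)
  pow_n <- sapply(c(10, 20, 45, 90, 200), function(n)
    posthoc_power_point_biserial(0.45, 0.05, n))
  expect_true(all(diff(pow_n) > 0))
  pow_r <- sapply(c(0.1, 0.25, 0.45, 0.6, 0.8), function(r)
    posthoc_power_point_biserial(r, 0.05, 45))
  expect_true(all(diff(pow_r) > 0))
  # Monte-Carlo oracle: two-sample design with n1 = 22, n2 = 23 whose
  # point-biserial effect is r = 0.45
  set.seed(38)
  r <- 0.45; n <- 45; n1 <- 22; n2 <- 23
  d <- 2 * r / sqrt(1 - r^2) * sqrt(n^2 / (4 * n1 * n2))
  reps <- 100000
  m1 <- matrix(rnorm(n1 * reps, d), n1)
  m2 <- matrix(rnorm(n2 * reps, 0), n2)
  s2p <- ((n1 - 1) * apply(m1, 2, var) + (n2 - 1) * apply(m2, 2, var)) /
    (n - 2)
  tstat <- (colMeans(m1) - colMeans(m2)) / sqrt(s2p * (1 / n1 + 1 / n2))
  mc <- mean(abs(tstat) > qt(0.975, n - 2))
  expect_equal(posthoc_power_point_biserial(0.45, 0.05, 45), mc,
               tolerance = 0.005)
  # the conservative bivariate-normal approximation sits a little lower
  fz <- posthoc_power_point_biserial(0.45, 0.05, 45, model = "fisher_z")
  expect_lt(fz, posthoc_power_point_biserial(0.45, 0.05, 45))
  expect_equal(fz, 0.88, tolerance = 0.01)
})

test_that("the agreement fit is exact for identical scores and reproducible", {
  set.seed(39)
  sc <- data.frame(overall = sample(2:7, 45, replace = TRUE),
                   trunk = sample(1:3, 45, replace = TRUE))
  fit <- rula_agreement(sc, sc)
  co <- coef(fit)
  expect_equal(co$kappa, c(1, 1))
  expect_equal(co$mean_diff, c(0, 0))
  expect_equal(co$rank_biserial, c(0, 0))
  expect_equal(fit$bonferroni_m, 2L)
  # kappa p-values carry the family-size correction
  expect_equal(co$kappa_pB, pmin(1, co$kappa_p * 2))
  # determinism of the full report on the same data
  expect_equal(coef(rula_agreement(sc, sc)), co)
})

test_that("rounding continuous aggregates to levels is half-up and clamped", {
  expect_equal(rulagree:::.round_levels(c(1.4, 1.5, 6.49, 6.5, 9, 0.2), 7L),
               c(1L, 2L, 6L, 7L, 7L, 1L))
})
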