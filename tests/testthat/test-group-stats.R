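# Nonparametric statistics layer.

test_that("Kruskal-Wallis matches hand formulas and the reference oracle", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_lt(kruskal_wallis(same)$statistic, 1e-9 + 0.3) # near-zero H with ties
  expect_gt(kruskal_wallis(same)$p, 0.5)

  # maximal rank separation: hand-computed H
  g <- list(1:3, 101:103, 201:203)
  N <- 9
  rank_sums <- c(sum(1:3), sum(4:6), sum(7:9))
  H_hand <- 12 / (N * (N + 1)) * sum(rank_sums^2 / 3) - 3 * (N + 1)
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, H_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)

  # tie-corrected H vs stats::kruskal.test on random data with ties
  set.seed(30)
  for (i in 1:5) {
    x <- list(sample(1:6, 12, TRUE), sample(2:8, 9, TRUE),
              sample(1:9, 10, TRUE))
    ref <- kruskal.test(x)
    mine <- kruskal_wallis(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }

  # rank invariance under monotone transforms
  x <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(x)$statistic,
               kruskal_wallis(lapply(x, function(v) exp(v)))$statistic,
               tolerance = 1e-12)

  expect_warning(kruskal_wallis(list(c(2, 2), c(2, 2, 2))), "identical")
  expect_error(kruskal_wallis(list(1:3)), class = "erpdyn_invalid_argument")
})

test_that("Dunn-Sidak pairwise comparisons follow Dunn's formulas", {
  # identical groups: adjusted p ~ 1
  same <- list(a = rep(c(1, 2, 3), 3), b = rep(c(1, 2, 3), 3),
               c = rep(c(1, 2, 3), 3))
  expect_true(all(dunn_sidak(same)$p_adj > 0.95))

  # Sidak closed form: m = 3, raw p = 0.05 -> 0.142625
  expect_equal(1 - (1 - 0.05)^3, 0.142625, tolerance = 1e-9)

  # independent re-computation of Dunn's z on a small 3-group dataset
  g <- list(a = c(1.1, 3.2, 2.0, 4.5), b = c(2.2, 5.1, 6.3, 7.0),
            c = c(0.5, 1.7, 2.1, 8.8))
  res <- dunn_sidak(g)
  x <- unlist(g); grp <- rep(names(g), each = 4)
  r <- rank(x); N <- length(x)
  ties <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (row in seq_len(nrow(res))) {
    i <- res$group1[row]; j <- res$group2[row]
    z_hand <- (mean(r[grp == i]) - mean(r[grp == j])) /
      sqrt(sigma2 * (1 / 4 + 1 / 4))
    p_hand <- 2 * pnorm(-abs(z_hand))
    expect_equal(res$z[row], z_hand, tolerance = 1e-8)
    expect_equal(res$p_adj[row], min(1, 1 - (1 - p_hand)^3), tolerance = 1e-8)
    expect_gte(res$p_adj[row], res$p[row]) # adjusted >= raw
  }
})

test_that("BH FDR reproduces closed forms and brute-force step-up", {
  # ten equal p-values: step-up minimum over j >= i gives p * m / m = p
  # (verified against p.adjust), and everything is rejected at q = 0.05
  res <- fdr_bh(rep(0.001, 10), q = 0.05)
  expect_true(all(res$rejected))
  expect_equal(res$p_adj, p.adjust(rep(0.001, 10), "BH"), tolerance = 1e-12)
  expect_true(all(abs(res$p_adj - 0.001) < 1e-12))

  expect_equal(fdr_bh(0.2)$p_adj, 0.2)

  p <- c(0.01, 0.02, 0.03, 0.5)
  res2 <- fdr_bh(p, q = 0.05)
  # brute-force step-up: largest k with p_(k) <= k q / m
  m <- length(p)
  ok <- which(sort(p) <= seq_len(m) * 0.05 / m)
  k <- if (length(ok)) max(ok) else 0
  brute_rej <- p <= (if (k > 0) sort(p)[k] else -1)
  expect_equal(res2$rejected, brute_rej)
  expect_equal(res2$p_adj, p.adjust(p, "BH"), tolerance = 1e-12)

  # random vectors against p.adjust
  set.seed(31)
  for (i in 1:5) {
    pv <- runif(20)^2
    expect_equal(fdr_bh(pv)$p_adj, p.adjust(pv, "BH"), tolerance = 1e-12)
  }
  expect_length(fdr_bh(numeric(0))$p_adj, 0)
})

test_that("Pearson and partial correlations agree with construction", {
  x <- c(1, 2, 4, 6, 9)
  res <- pearson_corr(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-6)

  # x and y conditionally independent given z
  set.seed(32)
  n <- 1000
  z <- rnorm(n)
  x2 <- z + rnorm(n)
  y2 <- z + rnorm(n)
  expect_gt(abs(pearson_corr(x2, y2)$r), 0.3) # marginally correlated
  expect_lt(abs(partial_corr(x2, y2, z)$r), 0.1)

  # no covariates reduces to plain Pearson
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(partial_corr(a, b), pearson_corr(a, b))

  expect_error(pearson_corr(rep(1, 5), rnorm(5)),
               class = "erpdyn_undefined_value")
})

test_that("chi-square contingency test reproduces printed and oracle values", {
  gender <- matrix(c(52, 44, 32, 19, 18, 10), ncol = 2)
  res <- chi_square_contingency(gender)
  expect_equal(round(res$p, 4), 0.8402)
  expect_equal(res$df, 2)
  ref <- suppressWarnings(chisq.test(gender, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)

  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_lt(chi_square_contingency(prop)$statistic, 1e-9)
  expect_equal(chi_square_contingency(prop)$p, 1, tolerance = 1e-9)

  diagt <- matrix(c(10, 0, 0, 10), 2)
  res2 <- chi_square_contingency(diagt)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$p, pchisq(20, 1, lower.tail = FALSE))

  expect_error(chi_square_contingency(matrix(c(1, 2, 0, 0), 2)),
               class = "erpdyn_invalid_argument")
})

test_that("ANOVA sample-size search reproduces the G*Power convention", {
  res <- anova_required_n(0.25, 0.05, 0.80, 3)
  expect_equal(res$N, 159)
  expect_gte(res$power, 0.80)

  # larger effect -> smaller N
  expect_lt(anova_required_n(0.4, 0.05, 0.80, 3)$N, 159)

  # power function against an independent noncentral-F series oracle
  ncf_cdf <- function(x, df1, df2, ncp, terms = 200) {
    j <- 0:terms
    w <- dpois(j, ncp / 2)
    sum(w * pbeta(df1 * x / (df1 * x + df2), df1 / 2 + j, df2 / 2))
  }
  N <- anova_required_n(0.40, 0.05, 0.80, 3)$N
  for (NN in c(N - 3, N)) {
    crit <- qf(0.95, 2, NN - 3)
    oracle <- 1 - ncf_cdf(crit, 2, NN - 3, 0.16 * NN)
    expect_equal(anova_power(NN, 0.40, 0.05, 3), oracle, tolerance = 1e-8)
  }

  # unbalanced search finds the unconstrained minimum (158 for f = 0.25)
  expect_equal(anova_required_n(0.25, balanced = FALSE)$N, 158)
  expect_error(anova_required_n(-1), class = "erpdyn_invalid_argument")
})

test_that("Sidak-adjusted p dominates Bonferroni", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(1)
    m <- sample(2:10, 1)
    expect_lte(1 - (1 - p)^m, min(1, m * p) + 1e-12)
  }
})

test_that("Kruskal-Wallis type-I error and BH-FDR control calibrate", {
  set.seed(34)
  rejections <- vapply(seq_len(2000), function(i) {
    g <- list(rnorm(20), rnorm(20), rnorm(20))
    kruskal_wallis(g)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.035)
  expect_lt(mean(rejections), 0.065)

  # empirical FDR under independent nulls stays below q
  set.seed(35)
  fdps <- vapply(seq_len(2000), function(i) {
    pv <- runif(20) # all null
    rej <- fdr_bh(pv, q = 0.05)$rejected
    if (!any(rej)) 0 else 1 # all rejections are false discoveries here
  }, numeric(1))
  expect_lte(mean(fdps), 0.05 + 0.015)
})
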