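# Nonparametric statistics layer: tie-corrected Kruskal-Wallis,
# Dunn-Sidak post hoc comparisons, Benjamini-Hochberg FDR, Pearson and
# partial correlation, Pearson chi-square contingency test, and the
# noncentral-F a priori power / sample-size computation.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = groups - 1). All-identical data return H = 0, p = 1 with a
#' warning.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `statistic` (H), `df`, `p`, `n` (group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) abort_invalid("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 1) || sum(n) < 3) abort_invalid("need >= 1 obs per group, >= 3 total")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), n)
  N <- length(x)
  r <- rank(x)
  if (length(unique(x)) == 1) {
    warning("all observations identical; H = 0")
    return(list(statistic = 0, df = length(groups) - 1, p = 1, n = n))
  }
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / n) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  df <- length(groups) - 1
  list(statistic = H, df = df, p = pchisq(H, df, lower.tail = FALSE), n = n)
}

#' Dunn's pairwise rank comparisons with Sidak adjustment
#'
#' Dunn's z on mean ranks with tie-corrected pooled variance; raw
#' two-sided normal p-values are Sidak-adjusted over all
#' `choose(groups, 2)` comparisons: `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_sidak <- function(groups) {
  if (length(groups) < 2) abort_invalid("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  n <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), n)
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, factor(g, levels = names(groups)), mean)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  varterm <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  res <- lapply(pairs, function(pr) {
    se <- sqrt(varterm * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- (mean_rank[pr[1]] - mean_rank[pr[2]]) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = as.numeric(z),
               p = as.numeric(p),
               p_adj = min(1, 1 - (1 - p)^m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR step-up
#'
#' @param pvalues Numeric p-values in [0, 1]; NAs pass through.
#' @param q FDR level for the rejection flags (default 0.05).
#' @return List with `rejected` (logical) and `p_adj` (BH-adjusted).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(rejected = logical(0), p_adj = numeric(0)))
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) abort_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  p_adj <- rep(NA_real_, length(pvalues))
  p_adj[ok][o] <- adj
  list(rejected = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("x and y lengths differ")
  n <- length(x)
  if (n < 3) abort_invalid("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort_undefined("zero-variance input")
  r <- cor(x, y)
  list(r = r, p = pearson_p(r, n), n = n, df = n - 2)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after least-squares projection
#' onto the covariates plus an intercept; p from the t test with
#' `n - 2 - n_covariates` df. With no covariates this reduces exactly to
#' [pearson_corr()].
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame (n x c) or NULL.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(pearson_corr(x, y))
  Z <- cbind(1, as.matrix(covariates))
  n <- length(x)
  if (nrow(Z) != n || length(y) != n) abort_invalid("length mismatch")
  nc <- ncol(Z) - 1
  if (n < 3 + nc) abort_invalid("too few observations for the covariate count")
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (sd(rx) == 0 || sd(ry) == 0) abort_undefined("zero residual variance")
  r <- cor(rx, ry)
  df <- n - 2 - nc
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df), n = n, df = df)
}

#' Pearson chi-square test of a contingency table
#'
#' No continuity correction by default (a 2x2-only `correct` flag is
#' provided), matching the convention needed for multi-row tables.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @param correct Apply the Yates correction (2x2 tables only).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_contingency <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || nrow(tab) < 2 || ncol(tab) < 2)
    abort_invalid("need a non-negative table of at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort_invalid("zero marginal in the contingency table")
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  if (correct && all(dim(tab) == c(2, 2))) {
    stat <- sum((pmax(abs(tab - expected) - 0.5, 0))^2 / expected)
  } else {
    stat <- sum((tab - expected)^2 / expected)
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Power of the one-way ANOVA F test
#'
#' @param N Total sample size (balanced design assumed).
#' @param f Cohen's f effect size.
#' @param alpha Significance level.
#' @param k_groups Number of groups.
#' @return Power in [0, 1], from the noncentral-F distribution with
#'   noncentrality `f^2 * N`, df1 = k - 1, df2 = N - k.
#' @export
anova_power <- function(N, f, alpha, k_groups) {
  df1 <- k_groups - 1
  df2 <- N - k_groups
  if (df2 < 1) return(0)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = f^2 * N, lower.tail = FALSE)
}

#' Required total sample size for a one-way ANOVA
#'
#' Finds the smallest total N whose noncentral-F power reaches the
#' target. By default N is constrained to a multiple of `k_groups`
#' (balanced integer allocation, the G*Power convention for one-way
#' designs); `balanced = FALSE` increments N by 1.
#'
#' @param f Cohen's f (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param k_groups Number of groups (>= 2).
#' @param balanced Constrain N to multiples of `k_groups` (default TRUE).
#' @return List with `N`, `power` (achieved), `f`, `alpha`, `k_groups`.
#' @export
anova_required_n <- function(f, alpha = 0.05, power = 0.80, k_groups = 3,
                             balanced = TRUE) {
  if (f <= 0) abort_invalid("f must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    abort_invalid("alpha and power must lie in (0, 1)")
  if (k_groups < 2) abort_invalid("k_groups must be >= 2")
  step <- if (balanced) k_groups else 1L
  N <- k_groups + 2L
  if (balanced) N <- k_groups * ceiling(N / k_groups)
  repeat {
    pw <- anova_power(N, f, alpha, k_groups)
    if (pw >= power)
      return(list(N = N, power = pw, f = f, alpha = alpha,
                  k_groups = k_groups, balanced = balanced))
    N <- N + step
    if (N > 1e6) abort_invalid("target power unreachable within N <= 1e6")
  }
}
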