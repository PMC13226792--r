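# Three-group classification from projection-difference features:
# stratified repeated k-fold cross-validation of a linear SVM, with a
# label-shuffling chance baseline and rank-sum comparison.
#
# No SVM library is assumed: a small L2-regularized squared-hinge linear
# SVM (the LIBLINEAR L2R_L2LOSS primal) is fit by BFGS, combined
# one-vs-one with margin-sum tie-breaking. Deterministic given the data.

#' Build the subject x feature table from projection differences
#'
#' Features are the flattened K x T target-minus-standard projection
#' arrays (row-major over states, then time), or the K x 6 window means
#' when `window_average = TRUE` (24 features for K = 4).
#'
#' @param projection_differences Named list (by subject) of K x T
#'   matrices.
#' @param window_average Average each state's time course into six
#'   100-ms windows first.
#' @param t_ms Optional time axis (ms) for window averaging; defaults to
#'   an even 0-600 ms grid.
#' @return Numeric matrix, subjects x features, rownames = subject ids.
#' @export
build_features <- function(projection_differences, window_average = FALSE,
                           t_ms = NULL) {
  if (!length(projection_differences)) abort_invalid("no inputs")
  rows <- lapply(projection_differences, function(m) {
    if (window_average) {
      Tn <- ncol(m)
      tt <- if (is.null(t_ms)) seq(0, 600, length.out = Tn + 1)[-(Tn + 1)] else t_ms
      wm <- vapply(seq_len(6), function(w) {
        sel <- tt >= (w - 1) * 100 - 1e-9 & tt < w * 100 - 1e-9
        rowMeans(m[, sel, drop = FALSE])
      }, numeric(nrow(m)))
      as.vector(t(wm))
    } else as.vector(t(m))
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) abort_invalid("inconsistent feature lengths")
  out <- do.call(rbind, rows)
  rownames(out) <- names(projection_differences)
  out
}

# --- linear SVM (squared hinge, L2 penalty), binary, labels in {-1, +1} ---
svm_fit_binary <- function(X, y, C = 1) {
  d <- ncol(X)
  obj <- function(wb) {
    w <- wb[seq_len(d)]; b <- wb[d + 1]
    m <- 1 - y * (X %*% w + b)
    viol <- pmax(m, 0)
    0.5 * sum(w^2) + C * sum(viol^2)
  }
  grad <- function(wb) {
    w <- wb[seq_len(d)]; b <- wb[d + 1]
    m <- as.vector(1 - y * (X %*% w + b))
    viol <- pmax(m, 0)
    gw <- w - 2 * C * as.vector(t(X) %*% (y * viol))
    gb <- -2 * C * sum(y * viol)
    c(gw, gb)
  }
  fit <- optim(numeric(d + 1), obj, grad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1])
}

# one-vs-one multiclass linear SVM with training-fold standardization
svm_train <- function(X, y, C = 1) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1], 1, -1)
    c(svm_fit_binary(Xs[sel, , drop = FALSE], yy, C), list(pair = pr))
  })
  list(models = models, classes = classes, mu = mu, sd = sdv)
}

svm_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, "/")
  votes <- matrix(0, nrow(X), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  margin <- votes
  for (m in fit$models) {
    f <- as.vector(Xs %*% m$w + m$b)
    win <- ifelse(f >= 0, m$pair[1], m$pair[2])
    for (i in seq_len(nrow(X)))
      votes[i, win[i]] <- votes[i, win[i]] + 1
    margin[, m$pair[1]] <- margin[, m$pair[1]] + f
    margin[, m$pair[2]] <- margin[, m$pair[2]] - f
  }
  # ties in votes broken by summed signed margins
  apply(votes + 1e-6 * margin / (1 + abs(margin)), 1L,
        function(v) fit$classes[which.max(v)])
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

cv_once <- function(X, y, folds, C = 1) {
  fold <- stratified_folds(y, folds)
  correct <- 0L
  for (f in seq_len(folds)) {
    te <- fold == f
    if (!any(te)) next
    fit <- svm_train(X[!te, , drop = FALSE], y[!te], C)
    pred <- svm_predict(fit, X[te, , drop = FALSE])
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Repeated stratified cross-validation of the linear SVM
#'
#' Per repeat: stratified fold assignment, per-feature standardization fit
#' on training folds only, linear SVM (one-vs-one) trained and evaluated
#' on held-out folds; the pooled held-out accuracy is recorded.
#'
#' @param features Subjects x features matrix.
#' @param labels Class labels (length = subjects).
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of repeats (default 500).
#' @param seed RNG seed.
#' @param C SVM regularization constant (default 1).
#' @return A `cv_result` with per-repeat `accuracy`, settings.
#' @export
cross_validate <- function(features, labels, folds = 10, repeats = 500,
                           seed = 1L, C = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) abort_invalid("need >= 2 classes")
  if (any(tab < folds))
    abort_invalid("every class needs >= `folds` subjects for stratification")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 400L))
  acc <- vapply(seq_len(repeats), function(i) cv_once(features, labels, folds, C),
                numeric(1))
  structure(list(accuracy = acc, folds = folds, repeats = repeats,
                 seed = seed, C = C),
            class = "cv_result")
}

#' Label-shuffled chance baseline with rank-sum comparison
#'
#' Labels are permuted independently in every repeat before
#' cross-validation; the shuffled accuracy distribution estimates chance
#' level. When `real` (a [cross_validate()] result) is supplied, a
#' two-sided Wilcoxon rank-sum test compares real vs shuffled accuracies.
#'
#' @inheritParams cross_validate
#' @param real Optional `cv_result` on the true labels.
#' @return A `cv_result` with `accuracy` (shuffled), and `p_vs_real` /
#'   `real_accuracy` when `real` is given.
#' @export
shuffled_baseline <- function(features, labels, folds = 10, repeats = 500,
                              seed = 1L, C = 1, real = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) abort_invalid("need >= 2 classes")
  if (any(tab < folds))
    abort_invalid("every class needs >= `folds` subjects for stratification")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 401L))
  acc <- vapply(seq_len(repeats), function(i) {
    yperm <- sample(labels)
    cv_once(features, yperm, folds, C)
  }, numeric(1))
  out <- list(accuracy = acc, folds = folds, repeats = repeats, seed = seed,
              C = C, shuffled = TRUE)
  if (!is.null(real)) {
    wt <- suppressWarnings(wilcox.test(real$accuracy, acc, exact = FALSE))
    out$p_vs_real <- wt$p.value
    out$real_accuracy <- mean(real$accuracy)
  }
  structure(out, class = "cv_result")
}
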