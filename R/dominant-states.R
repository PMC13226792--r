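# Data-driven dominant topographic states: PCA on the concatenated
# group-averaged responses (all groups x conditions, 0-600 ms), plus
# per-subject time-resolved projections onto the retained templates.

#' Average subject ERPs within group x condition cells
#'
#' @param erps List of `erp` objects carrying `group` and `condition`.
#' @return Named list (`"<group>|<condition>"`) of group-mean `erp`s.
#' @export
group_average_erps <- function(erps) {
  key <- vapply(erps, function(e) paste(e$group, e$condition, sep = "|"),
                character(1))
  lapply(split(erps, key), function(l) {
    e <- l[[1]]
    e$data <- Reduce(`+`, lapply(l, function(x) x$data)) / length(l)
    e$subject_id <- NA_character_
    e$n_trials_used <- NA_integer_
    e
  })
}

#' Extract K dominant topographic states
#'
#' Group-averaged responses (one `erp` per group x condition) are cropped
#' to the projection window, each instantaneous topography is centered
#' across channels, all samples are concatenated along time, and SVD
#' yields the top-K spatial loadings with their explained-variance
#' fractions. Signs follow the largest-magnitude-positive convention.
#'
#' @param erps List of `erp` objects (typically 3 groups x 2 conditions).
#' @param K Number of states to retain (default 4).
#' @param window_ms Projection window (default 0-600 ms, half-open).
#' @return A `state_basis`: `templates` (K x channels, channel-mean
#'   centered rows of unit norm), `explained_var` (all fractions, length
#'   min(rank)), `K`, `channel_names`, `provenance`.
#' @export
extract_states <- function(erps, K = 4, window_ms = c(0, 600)) {
  if (!length(erps)) abort_invalid("no ERPs given")
  ref <- erps[[1]]
  X <- do.call(rbind, lapply(erps, function(e) {
    match_montage(ref$channel_names, e$channel_names)
    t_ms <- e$t0_offset_ms + (seq_len(ncol(e$data)) - 1) * 1000 / e$fs
    sel <- t_ms >= window_ms[1] - 1e-9 & t_ms < window_ms[2] - 1e-9
    t(e$data[, sel, drop = FALSE])
  })) # (n_erps * T) x channels
  X <- X - rowMeans(X)
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < K)
    abort_invalid(sprintf("pooled responses have rank %d < K = %d", rank, K))
  templates <- t(sv$v[, seq_len(K), drop = FALSE])
  sgn <- apply(templates, 1L, function(v) sign(v[which.max(abs(v))]))
  templates <- templates * sgn
  rownames(templates) <- paste0("PC", seq_len(K))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(templates = templates, explained_var = ev, K = K,
                 channel_names = ref$channel_names,
                 provenance = sprintf("PCA on %d concatenated responses, %g-%g ms",
                                      length(erps), window_ms[1], window_ms[2]),
                 window_ms = window_ms),
            class = "state_basis")
}

#' Time-resolved projection of an ERP onto the state templates
#'
#' `coeffs[k, t]` is the dot product of template k with the channel-mean
#' centered instantaneous topography at sample t within the basis window.
#'
#' @param x An `erp`.
#' @param basis A `state_basis` with matching montage.
#' @return A `projection_timecourse`: `coeffs` (K x T), time axis, labels.
#' @export
project_timecourse <- function(x, basis) {
  match_montage(x$channel_names, basis$channel_names)
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  w <- basis$window_ms
  sel <- t_ms >= w[1] - 1e-9 & t_ms < w[2] - 1e-9
  topo <- x$data[, sel, drop = FALSE]
  topo <- sweep(topo, 2L, colMeans(topo))
  coeffs <- basis$templates %*% topo
  structure(list(coeffs = coeffs, t_ms = t_ms[sel], subject_id = x$subject_id,
                 group = x$group, condition = x$condition),
            class = "projection_timecourse")
}

#' Target-minus-standard projection difference
#'
#' @param target_tc,standard_tc `projection_timecourse` objects of the
#'   same subject and basis.
#' @return K x T matrix of differences.
#' @export
projection_difference <- function(target_tc, standard_tc) {
  if (!all(dim(target_tc$coeffs) == dim(standard_tc$coeffs)))
    abort_invalid("projection time courses have different shapes")
  target_tc$coeffs - standard_tc$coeffs
}

#' Polarity-ignored template-topography correlations with FDR
#'
#' `cell[k, w]` is |Pearson r| between template k and window-w topography
#' of a group-mean sequence; p-values use the two-sided t test on r with
#' `n_channels - 2` df (identical to the folded |r| null), and
#' significance applies BH-FDR over the K x 6 grid.
#'
#' @param basis A `state_basis`.
#' @param group_ts A [topo_sequence()] (typically a group mean).
#' @param q FDR level.
#' @return List with `r` (absolute correlations), `p`, `significant`.
#' @export
template_group_correlation <- function(basis, group_ts, q = 0.05) {
  match_montage(basis$channel_names, group_ts$channel_names)
  nch <- length(basis$channel_names)
  K <- basis$K; nw <- ncol(group_ts$topos)
  r <- p <- matrix(NA_real_, K, nw,
                   dimnames = list(rownames(basis$templates),
                                   colnames(group_ts$topos)))
  for (k in seq_len(K)) for (w in seq_len(nw)) {
    topo <- group_ts$topos[, w]
    if (sd(topo) == 0) next
    rr <- cor(basis$templates[k, ], topo)
    r[k, w] <- abs(rr)
    p[k, w] <- pearson_p(rr, nch)
  }
  fdr <- fdr_bh(as.vector(p), q = q)
  list(r = r, p = p, significant = matrix(fdr$rejected, K, nw,
                                          dimnames = dimnames(r)))
}

#' Per-state explained variance of a subject's response
#'
#' `fraction_k = sum_t coeffs[k, t]^2 / sum_t ||centered topo(t)||^2`;
#' fractions sum to at most 1, with equality iff the response lies in the
#' template span.
#'
#' @inheritParams project_timecourse
#' @return Length-K numeric vector of variance fractions.
#' @export
subject_variance_explained <- function(x, basis) {
  tc <- project_timecourse(x, basis)
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  w <- basis$window_ms
  sel <- t_ms >= w[1] - 1e-9 & t_ms < w[2] - 1e-9
  topo <- x$data[, sel, drop = FALSE]
  topo <- sweep(topo, 2L, colMeans(topo))
  total <- sum(topo^2)
  if (total == 0) abort_undefined("zero-energy response")
  out <- rowSums(tc$coeffs^2) / total
  names(out) <- rownames(basis$templates)
  out
}
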