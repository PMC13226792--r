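# Time-resolved topographic correlation analysis across the six 100-ms
# windows, between and within groups, with BH-FDR over the 6 x 6 grid.

#' Element-wise mean of topography sequences across subjects
#'
#' @param toposequences List of [topo_sequence()] objects with identical
#'   montage and window layout.
#' @return A single averaged `topo_sequence`.
#' @export
group_mean_toposequence <- function(toposequences) {
  if (!length(toposequences)) abort_invalid("need >= 1 toposequence")
  ref <- toposequences[[1]]
  for (ts in toposequences[-1])
    match_montage(ref$channel_names, ts$channel_names)
  acc <- Reduce(`+`, lapply(toposequences, function(ts) ts$topos))
  topo_sequence(acc / length(toposequences), channel_names = ref$channel_names,
                window_edges = ref$window_edges, group = ref$group,
                condition = ref$condition)
}

#' Window-by-window spatial correlation matrix between two sequences
#'
#' `r[i, j]` is the Pearson correlation across channels between window i
#' of `seqA` and window j of `seqB`; p-values come from the two-sided t
#' test with `n_channels - 2` degrees of freedom, and significance from
#' Benjamini-Hochberg FDR over all 36 cells.
#'
#' @param seqA,seqB [topo_sequence()] objects sharing the montage.
#' @param q FDR level (default 0.05).
#' @return A `corr_matrix` list: `r`, `p`, `significant` (6 x 6),
#'   axis labels. Zero-variance windows give NA cells.
#' @export
cross_corr_matrix <- function(seqA, seqB, q = 0.05) {
  match_montage(seqA$channel_names, seqB$channel_names)
  nch <- length(seqA$channel_names)
  if (nch < 3) abort_invalid("need >= 3 channels for spatial correlation")
  nw <- ncol(seqA$topos)
  r <- p <- matrix(NA_real_, nw, nw,
                   dimnames = list(colnames(seqA$topos), colnames(seqB$topos)))
  for (i in seq_len(nw)) for (j in seq_len(nw)) {
    a <- seqA$topos[, i]; b <- seqB$topos[, j]
    if (sd(a) == 0 || sd(b) == 0) next
    r[i, j] <- cor(a, b)
    p[i, j] <- pearson_p(r[i, j], nch)
  }
  fdr <- fdr_bh(as.vector(p), q = q)
  sig <- matrix(fdr$rejected, nw, nw)
  structure(list(r = r, p = p, significant = sig, q = q,
                 row_axis = paste(seqA$group, seqA$condition),
                 col_axis = paste(seqB$group, seqB$condition)),
            class = "corr_matrix")
}

# two-sided p for a Pearson r with df = n - 2
pearson_p <- function(r, n) {
  df <- n - 2
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tt), df)
}

#' Row-wise maximal-correlation alignment and its diagonal displacement
#'
#' For each row the column of maximal correlation is located (ties to the
#' smallest column); displacement is the mean over rows of
#' `|row - argmax|`. For within-group self-correlation matrices the
#' trivially-1 diagonal must be excluded.
#'
#' @param cm A `corr_matrix`.
#' @param exclude_diagonal Exclude `r[i, i]` from each row's maximum.
#' @return List with `argmax` (per-row column indices, NA for undefined
#'   rows) and `displacement` (mean absolute offset).
#' @export
max_alignment_displacement <- function(cm, exclude_diagonal = FALSE) {
  r <- cm$r
  nw <- nrow(r)
  argmax <- rep(NA_integer_, nw)
  for (i in seq_len(nw)) {
    row <- r[i, ]
    if (exclude_diagonal) row[i] <- NA
    if (all(is.na(row))) {
      warning(sprintf("row %d has no defined correlations; skipped", i))
      next
    }
    argmax[i] <- which.max(replace(row, is.na(row), -Inf))
  }
  ok <- !is.na(argmax)
  list(argmax = argmax,
       displacement = mean(abs(seq_len(nw)[ok] - argmax[ok])))
}
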