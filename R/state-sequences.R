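# Microstate-inspired discretization: each sample's topography is assigned
# to the best-matching template by polarity-invariant correlation, with an
# "Other" label for samples not significantly matching any template, and
# transition statistics computed from the resulting label sequences.

OTHER_STATE <- "Other"

#' Critical |r| for a two-sided Pearson test
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom (`n_channels - 2`).
#' @return The smallest |r| significant at `alpha`.
#' @export
critical_r <- function(alpha, df) {
  tq <- qt(1 - alpha / 2, df)
  sqrt(tq^2 / (tq^2 + df))
}

#' Assign each sample to a dominant state or "Other"
#'
#' At each sample within the basis window the channel-mean-centered
#' topography is correlated with every template; if the largest |r|
#' exceeds the two-sided critical r at `alpha` (df = channels - 2) the
#' sample takes that state's label (ties toward the lowest-index state),
#' otherwise "Other". Zero-variance topographies become "Other" with a
#' warning.
#'
#' @param x An `erp`.
#' @param basis A `state_basis`.
#' @param alpha Per-sample significance level (default 0.05, uncorrected).
#' @return A `state_seq`: `labels` (factor over PC1..PCK, Other), time
#'   axis, `alpha`, metadata.
#' @export
assign_states <- function(x, basis, alpha = 0.05) {
  match_montage(x$channel_names, basis$channel_names)
  nch <- length(x$channel_names)
  if (nch < 4) abort_invalid("state assignment needs >= 4 channels")
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  w <- basis$window_ms
  sel <- t_ms >= w[1] - 1e-9 & t_ms < w[2] - 1e-9
  topo <- x$data[, sel, drop = FALSE]
  topo <- sweep(topo, 2L, colMeans(topo))
  rc <- critical_r(alpha, nch - 2)
  state_names <- rownames(basis$templates)
  lv <- c(state_names, OTHER_STATE)

  sds <- apply(topo, 2L, sd)
  labels <- character(ncol(topo))
  # |r| against every template, vectorized over samples
  tz <- t(scale(t(basis$templates))) # row-standardized templates
  for (s in seq_len(ncol(topo))) {
    if (sds[s] == 0) {
      labels[s] <- OTHER_STATE
      next
    }
    z <- (topo[, s] - mean(topo[, s])) / sd(topo[, s])
    rs <- abs(as.vector(tz %*% z) / (nch - 1))
    best <- which.max(rs)
    labels[s] <- if (rs[best] > rc) state_names[best] else OTHER_STATE
  }
  if (any(sds == 0)) warning("zero-variance topographies labeled Other")
  structure(list(labels = factor(labels, levels = lv), t_ms = t_ms[sel],
                 alpha = alpha, subject_id = x$subject_id, group = x$group,
                 condition = x$condition, states = state_names),
            class = "state_seq")
}

#' Transition matrix of a state sequence
#'
#' Counts consecutive label pairs (self-pairs included) at full sample
#' resolution and row-normalizes. Rows of never-left states are NA.
#'
#' @param seq A `state_seq` (or plain factor/character vector of labels).
#' @param states State ordering; defaults to the sequence's levels.
#' @return A `transition_matrix`: `P` (row-stochastic where defined),
#'   `counts`, `n_transitions`.
#' @export
transition_matrix <- function(seq, states = NULL) {
  labels <- if (inherits(seq, "state_seq")) as.character(seq$labels)
            else as.character(seq)
  if (length(labels) < 2) abort_invalid("sequence must have >= 2 samples")
  if (is.null(states)) {
    states <- if (inherits(seq, "state_seq")) levels(seq$labels)
              else unique(labels)
  }
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  from <- labels[-length(labels)]
  to <- labels[-1]
  for (i in seq_along(from))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(P = P, counts = counts, n_transitions = length(from),
                 states = states),
            class = "transition_matrix")
}

#' Self-transition (stability) probabilities
#'
#' @param tm A `transition_matrix`.
#' @return Named vector of diagonal probabilities; NA for unvisited states.
#' @export
state_stability <- function(tm) {
  out <- diag(tm$P)
  names(out) <- tm$states
  out
}

#' Probability of one directed transition
#'
#' @param tm A `transition_matrix`.
#' @param from_state,to_state State labels.
#' @return `P[from, to]`; errors if the source state has no outgoing
#'   transitions.
#' @export
transition_probability <- function(tm, from_state, to_state) {
  if (!from_state %in% tm$states || !to_state %in% tm$states)
    abort_invalid("unknown state label")
  val <- tm$P[from_state, to_state]
  if (is.na(val))
    abort_undefined(sprintf("state '%s' has no outgoing transitions", from_state))
  val
}

#' Fraction of samples labeled "Other"
#'
#' @param seq A `state_seq` (or label vector).
#' @return Proportion in [0, 1].
#' @export
other_proportion <- function(seq) {
  labels <- if (inherits(seq, "state_seq")) as.character(seq$labels)
            else as.character(seq)
  if (!length(labels)) abort_invalid("empty sequence")
  mean(labels == OTHER_STATE)
}
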