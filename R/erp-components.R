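# Conventional ERP quantification: N200 / P300 mean amplitude, peak
# latency, and inter-trial topographic similarity.

#' Define an ERP component of interest
#'
#' @param name Component label, e.g. "N200".
#' @param condition Eliciting condition ("standard" or "target").
#' @param window_ms Half-open analysis window in ms, within 0-600.
#' @param polarity "negative" (peak = minimum) or "positive" (maximum).
#' @return A `component_spec`.
#' @export
component_spec <- function(name, condition, window_ms, polarity) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  if (window_ms[1] < 0 || window_ms[2] > 600 || window_ms[1] >= window_ms[2])
    abort_invalid("component window must lie within 0-600 ms")
  structure(list(name = name, condition = condition, window_ms = window_ms,
                 polarity = polarity), class = "component_spec")
}

#' Standard component definitions
#'
#' N200: standard stimuli, 150-250 ms, negative. P300: target stimuli,
#' 250-450 ms, positive.
#' @return Named list of [component_spec()] objects.
#' @export
standard_components <- function() {
  list(N200 = component_spec("N200", "standard", c(150, 250), "negative"),
       P300 = component_spec("P300", "target", c(250, 450), "positive"))
}

window_samples <- function(t_ms, window_ms) {
  sel <- t_ms >= window_ms[1] - 1e-9 & t_ms < window_ms[2] - 1e-9
  if (!any(sel)) abort_invalid("component window outside the ERP")
  sel
}

#' Per-channel mean amplitude within a component window
#'
#' @param x An `erp`.
#' @param spec A [component_spec()].
#' @return Named numeric vector, one mean amplitude (uV) per channel.
#' @export
component_amplitude <- function(x, spec) {
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  sel <- window_samples(t_ms, spec$window_ms)
  out <- rowMeans(x$data[, sel, drop = FALSE])
  names(out) <- x$channel_names
  out
}

#' Per-channel peak latency within a component window
#'
#' The peak is the window minimum for negative components and the maximum
#' for positive ones; ties break toward the earliest sample.
#'
#' @inheritParams component_amplitude
#' @return Named numeric vector of latencies (ms).
#' @export
component_latency <- function(x, spec) {
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  sel <- which(window_samples(t_ms, spec$window_ms))
  seg <- x$data[, sel, drop = FALSE]
  pick <- if (spec$polarity == "negative") max.col(-seg, ties.method = "first")
          else max.col(seg, ties.method = "first")
  out <- t_ms[sel[pick]]
  names(out) <- x$channel_names
  out
}

#' Inter-trial topographic similarity within a component window
#'
#' Each trial's window-mean topography (channel-mean-centered) is
#' correlated with the leave-one-out average of all other trials'
#' topographies; the mean over trials is returned. An all-pairs mean
#' correlation variant is available for sensitivity checks.
#'
#' @param epochs An `epoch_set` with at least 2 trials.
#' @param spec A [component_spec()].
#' @param method "loo" (default, leave-one-out vs rest) or "pairwise".
#' @param center Center topographies across channels first (default TRUE).
#' @return Scalar similarity in [-1, 1].
#' @export
intertrial_topographic_similarity <- function(epochs, spec,
                                              method = c("loo", "pairwise"),
                                              center = TRUE) {
  method <- match.arg(method)
  n_tr <- dim(epochs$data)[3]
  if (n_tr < 2) abort_invalid("similarity needs >= 2 trials")
  t_ms <- epoch_times(epochs)
  sel <- window_samples(t_ms, spec$window_ms)
  topos <- apply(epochs$data[, sel, , drop = FALSE], c(1, 3), mean) # ch x tr
  if (center) topos <- sweep(topos, 2L, colMeans(topos))
  sds <- apply(topos, 2L, sd)
  if (any(sds == 0)) {
    warning("zero-variance trial topography skipped")
    topos <- topos[, sds > 0, drop = FALSE]
    if (ncol(topos) < 2) abort_invalid("fewer than 2 usable trials")
  }
  if (method == "pairwise") {
    cm <- cor(topos)
    return(mean(cm[upper.tri(cm)]))
  }
  tot <- rowSums(topos)
  n <- ncol(topos)
  rs <- vapply(seq_len(n), function(i) {
    rest <- (tot - topos[, i]) / (n - 1)
    if (sd(rest) == 0) return(NA_real_)
    cor(topos[, i], rest)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}
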