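# Epoch containers and deterministic preprocessing:
# reference -> (optional band-pass) -> baseline -> amplitude rejection ->
# condition averaging -> window downsampling.

#' Construct an epoched-EEG container
#'
#' @param data Numeric array, channels x samples x trials (uV).
#' @param channel_names Ordered electrode labels.
#' @param fs Sampling rate (Hz).
#' @param t0_offset_ms Time of the first sample relative to stimulus onset.
#' @param subject_id,group,condition Metadata carried through the pipeline.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, channel_names, fs, t0_offset_ms,
                      subject_id = NA_character_, group = NA_character_,
                      condition = NA_character_) {
  if (length(dim(data)) != 3L)
    abort_invalid("epoch data must be a 3-d array (channels x samples x trials)")
  if (dim(data)[1] != length(channel_names))
    abort_invalid("channel_names length must match dim(data)[1]")
  if (anyDuplicated(channel_names))
    abort_invalid("channel_names must be unique")
  if (!all(is.finite(data))) abort_invalid("epoch data must be finite")
  structure(list(data = data, channel_names = channel_names, fs = fs,
                 t0_offset_ms = t0_offset_ms, subject_id = subject_id,
                 group = group, condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s/%s/%s: %d ch x %d samples x %d trials @ %g Hz, t0 %g ms\n",
              x$subject_id, x$group, x$condition, d[1], d[2], d[3], x$fs,
              x$t0_offset_ms))
  invisible(x)
}

#' Construct a trial-averaged ERP
#'
#' @param data Channels x samples matrix (uV).
#' @param channel_names,fs,t0_offset_ms,subject_id,group,condition As in
#'   [epoch_set()].
#' @param n_trials_used Number of trials entering the average.
#' @return An `erp` object.
#' @export
erp <- function(data, channel_names, fs, t0_offset_ms,
                subject_id = NA_character_, group = NA_character_,
                condition = NA_character_, n_trials_used = NA_integer_) {
  if (!is.matrix(data)) abort_invalid("ERP data must be a channels x samples matrix")
  if (!is.na(n_trials_used) && n_trials_used < 1)
    abort_invalid("n_trials_used must be >= 1")
  structure(list(data = data, channel_names = channel_names, fs = fs,
                 t0_offset_ms = t0_offset_ms, subject_id = subject_id,
                 group = group, condition = condition,
                 n_trials_used = n_trials_used),
            class = "erp")
}

#' Construct a six-window topography sequence (T1-T6)
#'
#' @param topos Channels x 6 matrix of window-mean voltages (uV).
#' @param channel_names Electrode labels.
#' @param window_edges Window boundaries in ms (half-open windows).
#' @param subject_id,group,condition Metadata.
#' @return A `topo_sequence` object.
#' @export
topo_sequence <- function(topos, channel_names,
                          window_edges = seq(0, 600, by = 100),
                          subject_id = NA_character_, group = NA_character_,
                          condition = NA_character_) {
  if (ncol(topos) != length(window_edges) - 1L)
    abort_invalid("topos columns must match window count")
  colnames(topos) <- paste0("T", seq_len(ncol(topos)))
  structure(list(topos = topos, channel_names = channel_names,
                 window_edges = window_edges, subject_id = subject_id,
                 group = group, condition = condition),
            class = "topo_sequence")
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample and trial, the instantaneous mean across
#' channels. Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
common_average_reference <- function(epochs) {
  d <- epochs$data
  if (dim(d)[1] < 2) abort_invalid("common average needs >= 2 channels")
  mu <- colMeans(d) # samples x trials
  epochs$data <- d - aperm(array(mu, dim = dim(d)[c(2, 3, 1)]), c(3, 1, 2))
  epochs
}

#' Zero-phase band-pass filter
#'
#' Filters every channel/trial with a zero-phase frequency-domain filter:
#' the FFT is multiplied by a real transfer function that is 1 in the pass
#' band and rolls off with raised-cosine edges (10% of each corner
#' frequency wide), so no phase distortion is introduced. Equivalent in
#' contract to forward-backward IIR filtering. DC is fully removed.
#'
#' @param epochs An `epoch_set`.
#' @param lo_hz,hi_hz Pass-band corner frequencies (Hz). `hi_hz` is clipped
#'   to 0.99 x Nyquist with a warning when necessary.
#' @return The filtered `epoch_set`.
#' @export
bandpass <- function(epochs, lo_hz = 0.1, hi_hz = 100) {
  fs <- epochs$fs
  nyq <- fs / 2
  if (lo_hz <= 0 || hi_hz <= lo_hz) abort_invalid("need 0 < lo_hz < hi_hz")
  if (hi_hz >= nyq) {
    warning("hi_hz clipped to 0.99 x Nyquist")
    hi_hz <- 0.99 * nyq
  }
  n <- dim(epochs$data)[2]
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # two-sided spectrum folded
  H <- cosine_band(freqs, lo_hz, hi_hz)
  d <- epochs$data
  for (tr in seq_len(dim(d)[3])) {
    X <- t(apply(d[, , tr, drop = FALSE][, , 1], 1L,
                 function(x) Re(fft(fft(x) * H, inverse = TRUE) / n)))
    d[, , tr] <- X
  }
  epochs$data <- d
  epochs
}

# Raised-cosine band transfer function; edges span 10% of each corner
# frequency (at least 0.05 Hz) so very low corners still attenuate DC.
cosine_band <- function(f, lo, hi) {
  wlo <- max(0.1 * lo, 0.05)
  whi <- max(0.1 * hi, 0.05)
  H <- numeric(length(f))
  up <- f >= lo & f < lo + wlo
  H[f >= lo + wlo & f <= hi - whi] <- 1
  H[up] <- 0.5 * (1 - cos(pi * (f[up] - lo) / wlo))
  dn <- f > hi - whi & f <= hi
  H[dn] <- 0.5 * (1 - cos(pi * (hi - f[dn]) / whi))
  H[f < lo | f > hi] <- 0
  H
}

#' Baseline-correct epochs against a pre-stimulus window
#'
#' @param epochs An `epoch_set`.
#' @param baseline_window_ms Two-element ms window (default -200..0),
#'   half-open, that must lie within the epoch.
#' @return The corrected `epoch_set`; per channel/trial the baseline-window
#'   mean is zero.
#' @export
baseline_correct <- function(epochs, baseline_window_ms = c(-200, 0)) {
  t_ms <- epoch_times(epochs)
  sel <- t_ms >= baseline_window_ms[1] & t_ms < baseline_window_ms[2]
  if (!any(sel) || baseline_window_ms[1] < t_ms[1] ||
      baseline_window_ms[2] > t_ms[length(t_ms)] + 1000 / epochs$fs)
    abort_invalid("baseline window outside the epoch")
  d <- epochs$data
  base <- apply(d[, sel, , drop = FALSE], c(1, 3), mean) # ch x trials
  epochs$data <- d - aperm(array(base, dim = dim(d)[c(1, 3, 2)]), c(1, 3, 2))
  epochs
}

#' Reject trials by absolute amplitude
#'
#' A trial is removed iff its maximum absolute value over all channels and
#' samples is strictly greater than the threshold; boundary values are
#' retained. Surviving trials keep their order and values.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Positive rejection threshold (uV), default 500.
#' @return List with `epochs` (survivors) and `rejected` (1-based trial
#'   indices removed).
#' @export
reject_amplitude <- function(epochs, threshold_uv = 500) {
  if (threshold_uv <= 0) abort_invalid("threshold must be positive")
  peak <- apply(abs(epochs$data), 3L, max)
  rejected <- which(peak > threshold_uv)
  if (length(rejected) == dim(epochs$data)[3])
    abort_empty("all trials rejected")
  if (length(rejected))
    epochs$data <- epochs$data[, , -rejected, drop = FALSE]
  list(epochs = epochs, rejected = rejected)
}

#' Average trials into a condition ERP
#'
#' @param epochs An `epoch_set` with at least one trial.
#' @return An [erp()] with `n_trials_used` recorded.
#' @export
condition_average <- function(epochs) {
  n <- dim(epochs$data)[3]
  if (n < 1) abort_empty("no trials to average")
  erp(rowMeans(epochs$data, dims = 2L), channel_names = epochs$channel_names,
      fs = epochs$fs, t0_offset_ms = epochs$t0_offset_ms,
      subject_id = epochs$subject_id, group = epochs$group,
      condition = epochs$condition, n_trials_used = n)
}

#' Average an ERP into consecutive half-open time windows
#'
#' Default settings produce the six 100-ms windows T1-T6 covering
#' 0-600 ms; a sample at exactly a window edge belongs to the later window.
#'
#' @param x An `erp`.
#' @param start_ms,end_ms,width_ms Window layout; `width_ms` must divide
#'   `end_ms - start_ms`.
#' @return A [topo_sequence()].
#' @export
window_means <- function(x, start_ms = 0, end_ms = 600, width_ms = 100) {
  span <- end_ms - start_ms
  if (span <= 0 || abs(span / width_ms - round(span / width_ms)) > 1e-9)
    abort_invalid("width_ms must divide end_ms - start_ms")
  t_ms <- x$t0_offset_ms + (seq_len(ncol(x$data)) - 1) * 1000 / x$fs
  if (start_ms < t_ms[1] - 1e-9 || end_ms > t_ms[length(t_ms)] + 1000 / x$fs + 1e-9)
    abort_invalid("ERP does not cover the requested window span")
  nw <- as.integer(round(span / width_ms))
  topos <- vapply(seq_len(nw), function(w) {
    a <- start_ms + (w - 1) * width_ms
    sel <- t_ms >= a - 1e-9 & t_ms < a + width_ms - 1e-9
    rowMeans(x$data[, sel, drop = FALSE])
  }, numeric(nrow(x$data)))
  topo_sequence(topos, channel_names = x$channel_names,
                window_edges = seq(start_ms, end_ms, by = width_ms),
                subject_id = x$subject_id, group = x$group,
                condition = x$condition)
}

#' Downsample epochs by decimation with anti-alias low-pass
#'
#' Applies the zero-phase low-pass at 0.4 x target Nyquist roll-on of the
#' new rate, then keeps every `factor`-th sample. Intended for real
#' recordings; the synthetic path generates at the target rate directly.
#'
#' @param epochs An `epoch_set`.
#' @param factor Integer decimation factor >= 2.
#' @return The decimated `epoch_set`.
#' @export
downsample <- function(epochs, factor) {
  if (factor < 2 || factor != round(factor))
    abort_invalid("factor must be an integer >= 2")
  new_fs <- epochs$fs / factor
  hi <- 0.8 * new_fs / 2
  n <- dim(epochs$data)[2]
  freqs <- (seq_len(n) - 1) * epochs$fs / n
  freqs <- pmin(freqs, epochs$fs - freqs)
  whi <- 0.1 * hi
  H <- ifelse(freqs <= hi - whi, 1,
              ifelse(freqs <= hi, 0.5 * (1 - cos(pi * (hi - freqs) / whi)), 0))
  d <- epochs$data
  for (tr in seq_len(dim(d)[3]))
    d[, , tr] <- t(apply(d[, , tr, drop = FALSE][, , 1], 1L,
                         function(x) Re(fft(fft(x) * H, inverse = TRUE) / n)))
  keep <- seq(1, n, by = factor)
  epochs$data <- d[, keep, , drop = FALSE]
  epochs$fs <- new_fs
  epochs
}

#' Standard preprocessing chain
#'
#' Common-average reference, optional band-pass, baseline correction and
#' amplitude rejection, in that order. Filtering defaults off because the
#' generator produces band-limited signals.
#'
#' @param epochs An `epoch_set`.
#' @param filter Apply [bandpass()]? Default `FALSE`.
#' @param band Pass band (Hz) when filtering.
#' @param baseline_window_ms Baseline window; `NULL` skips correction.
#' @param reject_uv Rejection threshold (uV); `NULL` skips rejection.
#' @return The preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, filter = FALSE, band = c(0.1, 100),
                              baseline_window_ms = c(-200, 0),
                              reject_uv = 500) {
  out <- common_average_reference(epochs)
  if (filter) out <- bandpass(out, band[1], band[2])
  if (!is.null(baseline_window_ms))
    out <- baseline_correct(out, baseline_window_ms)
  if (!is.null(reject_uv)) out <- reject_amplitude(out, reject_uv)$epochs
  out
}
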