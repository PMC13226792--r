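#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Internal validation helpers shared across modules.

abort_invalid <- function(msg, class = "erpdyn_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_empty <- function(msg) abort_invalid(msg, class = "erpdyn_empty_result")
abort_format <- function(msg) abort_invalid(msg, class = "erpdyn_format_error")
abort_undefined <- function(msg) abort_invalid(msg, class = "erpdyn_undefined_value")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a finite numeric scalar", name))
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage
#' (and each subject within the generator) receives a distinct derived seed
#' via a fixed linear-congruential split, keeping every value below 2^31.
#'
#' @param seed Integer master seed.
#' @param offset Non-negative integer identifying the stage or unit.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, offset = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  # two rounds of a fixed LCG so nearby (seed, offset) pairs decorrelate
  s <- (s * 48271 + as.numeric(offset) * 16807 + 1) %% m
  s <- (s * 69621 + 12345) %% m
  as.integer(s)
}

# Sample time axis (ms) for an epoch container.
epoch_times <- function(x) {
  n <- dim(x$data)[2]
  x$t0_offset_ms + (seq_len(n) - 1L) * 1000 / x$fs
}

# Center a vector (or each column of a matrix) across channels.
center_channels <- function(x) {
  if (is.matrix(x)) sweep(x, 2L, colMeans(x)) else x - mean(x)
}

match_montage <- function(a_names, b_names, what = "montage") {
  if (length(a_names) != length(b_names) || !all(a_names == b_names))
    abort_invalid(sprintf("%s mismatch between inputs", what))
  invisible(TRUE)
}

#' Standard 19-channel 10-20 montage labels
#' @return Character vector of 19 electrode labels.
#' @export
montage_1020_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}
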