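# On-disk epoch container: little-endian float32 payload plus a JSON
# sidecar carrying shape and metadata. Payload order is column-major over
# (channels, samples, trials), matching the in-memory array.

container_paths <- function(dir, subject_id, condition) {
  stem <- file.path(dir, paste(subject_id, condition, sep = "_"))
  list(bin = paste0(stem, ".f32"), json = paste0(stem, ".json"))
}

#' Write an epoch set to the binary + JSON container
#'
#' @param epochs An `epoch_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
write_container <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- container_paths(dir, epochs$subject_id, epochs$condition)
  con <- file(pth$bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 4L, endian = "little")
  meta <- list(subject_id = epochs$subject_id, group = epochs$group,
               condition = epochs$condition,
               channel_names = epochs$channel_names,
               fs = epochs$fs, t0_offset_ms = epochs$t0_offset_ms,
               shape = dim(epochs$data), dtype = "float32-le",
               provenance = "erpdyn epoch container v1")
  jsonlite::write_json(meta, pth$json, auto_unbox = TRUE, digits = NA)
  invisible(pth)
}

#' Read an epoch set back from the container
#'
#' @param dir Container directory.
#' @param subject_id,condition Identify the record.
#' @return The reconstructed `epoch_set`. Signals a format error on
#'   missing sidecar, truncated payload, shape mismatch, or non-finite
#'   values.
#' @export
read_container <- function(dir, subject_id, condition) {
  pth <- container_paths(dir, subject_id, condition)
  if (!file.exists(pth$json)) abort_format("missing sidecar JSON")
  if (!file.exists(pth$bin)) abort_format("missing binary payload")
  meta <- jsonlite::read_json(pth$json, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L || any(shape < 1L))
    abort_format("sidecar shape must be 3 positive integers")
  n <- prod(shape)
  sz <- file.info(pth$bin)$size
  if (sz != 4 * n)
    abort_format(sprintf("payload has %d bytes, expected %d", sz, 4 * n))
  con <- file(pth$bin, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (!all(is.finite(raw))) abort_format("non-finite values in payload")
  if (length(meta$channel_names) != shape[1])
    abort_format("channel_names length does not match payload shape")
  epoch_set(array(raw, dim = shape), channel_names = meta$channel_names,
            fs = meta$fs, t0_offset_ms = meta$t0_offset_ms,
            subject_id = meta$subject_id, group = meta$group,
            condition = meta$condition)
}

#' List subject/condition records present in a container directory
#'
#' @param dir Container directory.
#' @return Data frame with `subject_id`, `condition`, `group` per record.
#' @export
list_container <- function(dir) {
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  sidecars <- sidecars[basename(sidecars) != "ground_truth.json"]
  if (!length(sidecars))
    return(data.frame(subject_id = character(), condition = character(),
                      group = character()))
  recs <- lapply(sidecars, function(p) {
    meta <- jsonlite::read_json(p, simplifyVector = TRUE)
    data.frame(subject_id = meta$subject_id, condition = meta$condition,
               group = meta$group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out[order(out$subject_id, out$condition), , drop = FALSE]
}
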