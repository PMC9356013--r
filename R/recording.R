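#' Construct a multichannel extracellular recording
#'
#' A `neodev_recording` bundles a channels-by-samples voltage matrix with its
#' sampling rate, per-channel region labels, units, and optional interval
#' annotations. It is the substrate of every signal operation in the package.
#'
#' @param samples Numeric matrix, channels x time points. A vector is treated
#'   as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channels Tibble or data frame with columns `channel_id` and `region`;
#'   one row per matrix row. Defaults to `ch1..chN` all labelled `"PL"`.
#' @param units Unit string for the samples; `"uV"` for raw voltage traces,
#'   `"z"` after standardization.
#' @param start_time Recording start in seconds (default 0).
#' @param regions Allowed region vocabulary; prelimbic cortex and hippocampal
#'   CA1 by default, extensible for other preparations.
#' @param annotations Optional interval tibble (see [read_intervals()]).
#'
#' @return An object of class `neodev_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100,
#'                  channels = tibble::tibble(channel_id = c("pl1", "hp1"),
#'                                            region = c("PL", "HP")))
#' duration(rec)
recording <- function(samples, fs, channels = NULL, units = "uV",
                      start_time = 0, regions = c("PL", "HP"),
                      annotations = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x time).",
          class = "neodev_validation_error")
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    abort("`fs` must be a positive number.", class = "neodev_validation_error")
  }
  bad <- which(!is.finite(samples), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-finite sample at channel %d, index %d",
                  bad[1, 1], bad[1, 2]),
          class = "neodev_validation_error")
  }
  if (is.null(channels)) {
    channels <- tibble::tibble(
      channel_id = paste0("ch", seq_len(nrow(samples))),
      region = regions[1]
    )
  }
  channels <- tibble::as_tibble(channels)
  if (!all(c("channel_id", "region") %in% names(channels))) {
    abort("`channels` needs columns channel_id and region.",
          class = "neodev_validation_error")
  }
  if (nrow(channels) != nrow(samples)) {
    abort("channel table rows must equal sample matrix rows.",
          class = "neodev_validation_error")
  }
  if (!all(channels$region %in% regions)) {
    abort(sprintf("unknown region label(s): %s",
                  paste(setdiff(channels$region, regions), collapse = ", ")),
          class = "neodev_validation_error")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), channels = channels,
         units = units, start_time = as.numeric(start_time),
         regions = regions, annotations = annotations),
    class = "neodev_recording"
  )
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "neodev_recording"))
  ncol(rec$samples) / rec$fs
}

#' @export
print.neodev_recording <- function(x, ...) {
  cat(sprintf("<neodev_recording> %d channel(s), %.1f s at %g Hz [%s]\n",
              nrow(x$samples), duration(x), x$fs, x$units))
  print(x$channels, n = 5)
  invisible(x)
}

# Extract one channel's trace by id, with a clear error.
channel_trace <- function(rec, channel_id) {
  i <- match(channel_id, rec$channels$channel_id)
  if (is.na(i)) {
    abort(sprintf("channel '%s' not found", channel_id),
          class = "neodev_validation_error")
  }
  rec$samples[i, ]
}

# First channel id for a region (the region's designated analysis channel).
region_channel <- function(rec, region) {
  ids <- rec$channels$channel_id[rec$channels$region == region]
  if (length(ids) == 0) {
    abort(sprintf("no channel with region '%s'", region),
          class = "neodev_validation_error")
  }
  ids[[1]]
}
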