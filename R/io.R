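# Readers/writers for the package's plain-text exchange formats.
#
# Doubles are written with 17 significant digits so every value round-trips
# bit-for-bit through the text format.
format_csv_full <- function(tbl) {
  cols <- lapply(tbl, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  })
  header <- paste(names(tbl), collapse = ",")
  if (nrow(tbl) == 0) return(c(header, character(0)))
  c(header, do.call(paste, c(cols, sep = ",")))
}

# Signals: CSV body (one column per channel, one row per sample) preceded by
# `#key=value` comment lines carrying fs_hz, units, start_time and the
# channel -> region map. Tables (intervals, spikes, features): plain CSV with
# a mandatory header, UTF-8, '.' decimal. Units metadata is enforced on read;
# a file without a units line is a format error, never a silent default.

#' Write a recording to a self-describing CSV file
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "neodev_recording"))
  header <- c(
    sprintf("#fs_hz=%s", format(rec$fs, digits = 17)),
    sprintf("#units=%s", rec$units),
    sprintf("#start_time=%s", format(rec$start_time, digits = 17)),
    sprintf("#regions=%s", paste(rec$regions, collapse = ";")),
    sprintf("#channel_regions=%s",
            paste(rec$channels$channel_id, rec$channels$region,
                  sep = ":", collapse = ";"))
  )
  body <- tibble::as_tibble(t(rec$samples), .name_repair = "minimal")
  names(body) <- rec$channels$channel_id
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, format_csv_full(body)), con)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path File path.
#' @return A [recording()]; samples round-trip losslessly.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "neodev_io_error")
  }
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^#", key, "="), "", m[[1]])
  }
  units <- get("units")
  fs <- get("fs_hz")
  if (is.null(units) || is.null(fs)) {
    abort("recording file lacks fs_hz or units metadata",
          class = "neodev_format_error")
  }
  chmap <- get("channel_regions")
  pairs <- strsplit(strsplit(chmap, ";")[[1]], ":")
  channels <- tibble::tibble(
    channel_id = vapply(pairs, `[[`, "", 1),
    region = vapply(pairs, `[[`, "", 2)
  )
  regions <- strsplit(get("regions") %||% "PL;HP", ";")[[1]]
  body <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  samples <- t(as.matrix(body))
  dimnames(samples) <- NULL
  recording(samples, fs = as.numeric(fs), channels = channels, units = units,
            start_time = as.numeric(get("start_time") %||% "0"),
            regions = regions)
}

validate_intervals <- function(tbl, duration_s = NULL) {
  tbl <- tibble::as_tibble(tbl)
  bad <- which(!(tbl$start_s < tbl$end_s))
  if (length(bad) > 0) {
    abort(sprintf("interval row %d violates start_s < end_s", bad[[1]]),
          class = "neodev_validation_error")
  }
  if (!is.null(duration_s) && nrow(tbl) > 0 &&
      (min(tbl$start_s) < 0 || max(tbl$end_s) > duration_s + 1e-9)) {
    abort("interval outside [0, recording duration]",
          class = "neodev_validation_error")
  }
  tbl
}

#' Read or write an interval table
#'
#' Intervals are half-open `[start_s, end_s)` with a label and optional
#' channel and value columns; the carrier for detected active periods and
#' ground-truth burst annotations.
#'
#' @param path CSV path.
#' @param tbl Tibble with columns `start_s`, `end_s`, `label`, and optionally
#'   `channel_id`, `value`.
#' @return `read_intervals()` returns the tibble; `write_intervals()` returns
#'   `path` invisibly.
#' @export
read_intervals <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (nrow(tbl) == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          label = character()))
  }
  validate_intervals(tbl)
}

#' @rdname read_intervals
#' @export
write_intervals <- function(tbl, path) {
  validate_intervals(tbl)
  writeLines(format_csv_full(tibble::as_tibble(tbl)), path)
  invisible(path)
}

#' Read or write a spike-train table
#'
#' A spike train is a tibble of `{time_s, channel_id}` rows plus a recording
#' duration carried in the `duration_s` attribute.
#'
#' @param path CSV path.
#' @param spikes Spike tibble with attribute `duration_s`.
#' @param duration_s Recording duration; required on write if the attribute is
#'   absent.
#' @return The spike tibble (read) or `path` invisibly (write).
#' @export
read_spikes <- function(path) {
  lines <- readLines(path, n = 1)
  dur <- NULL
  if (grepl("^#duration_s=", lines[[1]])) {
    dur <- as.numeric(sub("^#duration_s=", "", lines[[1]]))
  }
  tbl <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                           check.names = FALSE))
  tbl <- dplyr::arrange(tbl, .data$channel_id, .data$time_s)
  if (!is.null(dur)) {
    if (nrow(tbl) > 0 && (min(tbl$time_s) < 0 || max(tbl$time_s) > dur)) {
      abort("spike time outside [0, duration]",
            class = "neodev_validation_error")
    }
    attr(tbl, "duration_s") <- dur
  }
  tbl
}

#' @rdname read_spikes
#' @export
write_spikes <- function(spikes, path, duration_s = NULL) {
  dur <- duration_s %||% attr(spikes, "duration_s")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(dur)) {
    writeLines(sprintf("#duration_s=%s", format(dur, digits = 17)), con)
  }
  writeLines(format_csv_full(tibble::as_tibble(spikes)), con)
  invisible(path)
}

#' Read or write a per-animal feature table
#'
#' One row per animal: identifiers, group label, and named numeric features;
#' the input to the group-comparison battery.
#'
#' @param path CSV path.
#' @param tbl Feature tibble; `animal_id` must be unique.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
read_features <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (anyDuplicated(tbl$animal_id)) {
    abort("duplicate animal_id in feature table",
          class = "neodev_validation_error")
  }
  tbl
}

#' @rdname read_features
#' @export
write_features <- function(tbl, path) {
  if (anyDuplicated(tbl$animal_id)) {
    abort("duplicate animal_id in feature table",
          class = "neodev_validation_error")
  }
  writeLines(format_csv_full(tibble::as_tibble(tbl)), path)
  invisible(path)
}

#' @importFrom rlang .data
NULL
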