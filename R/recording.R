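# Recording and firings containers.

#' Create a recording object
#'
#' A recording bundles a multichannel extracellular timeseries (microvolts)
#' with its sample rate and electrode geometry.
#'
#' @param traces Numeric matrix, channels x samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param geometry Numeric matrix of per-channel electrode coordinates in
#'   micrometers (one row per channel, 2 or 3 columns). Defaults to a vertical
#'   line with 20 um pitch.
#' @return An object of class `recording`.
#' @export
recording <- function(traces, sample_rate, geometry = NULL) {
  traces <- as.matrix(traces)
  stopifnot(is.numeric(traces), sample_rate > 0)
  if (is.null(geometry)) {
    geometry <- cbind(0, (seq_len(nrow(traces)) - 1L) * 20)
  }
  geometry <- as.matrix(geometry)
  if (nrow(geometry) != nrow(traces)) {
    stop("geometry row count (", nrow(geometry),
         ") must equal channel count (", nrow(traces), ")", call. = FALSE)
  }
  if (!ncol(geometry) %in% c(2L, 3L)) {
    stop("geometry must have 2 or 3 columns", call. = FALSE)
  }
  structure(
    list(traces = traces, sample_rate = as.numeric(sample_rate),
         geometry = geometry),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$traces), ncol(x$traces), x$sample_rate,
              ncol(x$traces) / x$sample_rate))
  invisible(x)
}

#' @rdname recording
#' @param x A `recording`.
#' @export
n_channels <- function(x) nrow(x$traces)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$traces)

#' @rdname recording
#' @export
duration_s <- function(x) ncol(x$traces) / x$sample_rate

#' Write a recording to disk
#'
#' Writes the timeseries as a float32 MDA file plus a JSON sidecar holding the
#' sample rate, electrode geometry and duration.
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if needed).
#' @param name Base name for the two files (`<name>.mda`, `<name>.json`).
#' @return Named list with the two file paths, invisibly.
#' @export
write_recording <- function(rec, dir, name = "recording") {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mda_path <- file.path(dir, paste0(name, ".mda"))
  json_path <- file.path(dir, paste0(name, ".json"))
  write_mda(rec$traces, mda_path, type = "float32")
  manifest <- list(
    sample_rate = rec$sample_rate,
    geometry = unname(apply(rec$geometry, 1L, as.list)),
    timeseries_uri = basename(mda_path),
    duration_samples = ncol(rec$traces)
  )
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(timeseries = mda_path, manifest = json_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param json_path Path to the JSON sidecar; the timeseries MDA is resolved
#'   relative to it.
#' @return A [recording()].
#' @export
read_recording <- function(json_path) {
  m <- jsonlite::read_json(json_path)
  if (is.null(m$sample_rate) || m$sample_rate <= 0) {
    stop("manifest must declare a positive sample_rate", call. = FALSE)
  }
  mda_path <- file.path(dirname(json_path), m$timeseries_uri)
  traces <- read_mda(mda_path)
  attr(traces, "mda_type") <- NULL
  geom <- do.call(rbind, lapply(m$geometry, function(p) unlist(p)))
  rec <- recording(traces, m$sample_rate, geom)
  if (!is.null(m$duration_samples) &&
      m$duration_samples != ncol(rec$traces)) {
    stop("manifest duration_samples disagrees with timeseries", call. = FALSE)
  }
  rec
}

#' Create a firings object
#'
#' Labeled spike events in the 3-row convention of the deposited firing files:
#' row 1 the primary channel (1-based, 0 if unknown), row 2 the event time as
#' a 1-based sample index (possibly fractional; floored when indexing traces),
#' row 3 the positive-integer unit label.
#'
#' @param channel Primary channel per event (0 allowed for unknown).
#' @param sample Event time in samples (1-based).
#' @param label Unit label per event (positive integers).
#' @return A 3 x L numeric matrix of class `firings` with rows
#'   `channel`, `sample`, `label`, ordered by time.
#' @export
firings <- function(channel, sample, label) {
  stopifnot(length(channel) == length(sample),
            length(sample) == length(label))
  if (length(label) && any(label < 1)) {
    stop("unit labels must be positive integers", call. = FALSE)
  }
  m <- rbind(channel = as.numeric(channel),
             sample = as.numeric(sample),
             label = as.numeric(label))
  if (ncol(m)) m <- m[, order(m["sample", ]), drop = FALSE]
  structure(m, class = "firings")
}

#' @export
print.firings <- function(x, ...) {
  cat(sprintf("<firings> %d events, %d units\n", ncol(x),
              length(unique(x["label", ]))))
  invisible(x)
}

#' @rdname firings
#' @param x A `firings` object.
#' @export
firings_labels <- function(x) sort(unique(x["label", ]))

#' Event times (samples) of one unit, in increasing order
#'
#' @param x A [firings()] object.
#' @param label Unit label.
#' @return Numeric vector of sample times.
#' @export
unit_times <- function(x, label) {
  t <- x["sample", x["label", ] == label]
  sort(t)
}

#' Read/write firings in MDA or CSV form
#'
#' MDA holds the raw 3 x L matrix; the CSV alternative has the header
#' `channel,sample,label`.
#'
#' @param path File path; format chosen by extension (`.mda` or `.csv`).
#' @return For `read_firings`, a [firings()] object.
#' @export
read_firings <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    stopifnot(all(c("channel", "sample", "label") %in% names(d)))
    firings(d$channel, d$sample, d$label)
  } else {
    m <- read_mda(path)
    if (nrow(m) != 3L) stop("firings MDA must be 3 x L", call. = FALSE)
    firings(m[1L, ], m[2L, ], m[3L, ])
  }
}

#' @rdname read_firings
#' @param f A [firings()] object.
#' @export
write_firings <- function(f, path) {
  stopifnot(inherits(f, "firings"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- data.frame(channel = f["channel", ], sample = f["sample", ],
                    label = f["label", ])
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    write_mda(unclass(f), path, type = "float64")
  }
  invisible(path)
}
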