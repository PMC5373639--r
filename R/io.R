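# Readers/writers. Signals travel as raw little-endian float32 binary with
# a JSON sidecar; everything tabular is CSV. Times are seconds (float64),
# sample indices 1-based in R code, 0-based in sidecars.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a continuous signal
#'
#' The binary file holds little-endian float32 samples; `<path>.json` holds
#' `fs_hz`, `n_samples`, `dtype`, `units` and `t0_s`. Storage is float32,
#' so a write-read cycle is bit-exact for float32-representable samples
#' (and idempotent in general).
#'
#' @param signal a [continuous_signal()].
#' @param path file path of the binary payload.
#' @return `load_signal` returns a [continuous_signal()];
#'   `save_signal` returns `path` invisibly.
#' @export
save_signal <- function(signal, path) {
  stopifnot(inherits(signal, "continuous_signal"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(signal$samples, con, size = 4L, endian = "little")
  meta <- list(fs_hz = signal$fs, n_samples = length(signal$samples),
               dtype = "float32", units = "uV", t0_s = signal$t0)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_signal
#' @export
load_signal <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("fs_hz", "n_samples")
  if (!all(need %in% names(meta)))
    stop("sidecar must contain fs_hz and n_samples")
  if (!is.null(meta$dtype) && meta$dtype != "float32")
    stop("unsupported dtype: ", meta$dtype)
  sz <- file.size(path)
  if (is.na(sz) || sz != 4L * meta$n_samples)
    stop("file size inconsistent with sidecar n_samples")
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_samples, size = 4L,
               endian = "little")
  if (anyNA(x) || !all(is.finite(x))) stop("signal contains NaN/Inf")
  continuous_signal(x, as.numeric(meta$fs_hz),
                    if (is.null(meta$t0_s)) 0 else as.numeric(meta$t0_s))
}

#' Write / read spike-time events
#'
#' CSV with a single `time_s` column, written at full float precision.
#'
#' @param train a [spike_train()].
#' @param path CSV path.
#' @param duration recording length in seconds, needed on load (the CSV
#'   carries only times); defaults to the last event time.
#' @return `load_events` returns a [spike_train()].
#' @export
save_events <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  writeLines(c("time_s", sprintf("%.17g", train$times)), path)
  invisible(path)
}

#' @rdname save_events
#' @export
load_events <- function(path, duration = NULL) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("events CSV must have a time_s column")
  tt <- as.numeric(df$time_s)
  if (anyNA(tt) || any(tt < 0)) stop("event times must be non-negative")
  if (is.unsorted(tt, strictly = TRUE) && length(tt) > 1L)
    stop("event times must be strictly increasing")
  if (is.null(duration)) duration <- if (length(tt)) max(tt) else 1
  spike_train(tt, duration)
}

#' Write / read a segment set
#'
#' Segments are a CSV matrix (one snippet per row, no header) plus a JSON
#' sidecar with `fs_hz`, `align_index` (0-based), `window_ms` and optional
#' `source_times_s`.
#'
#' @param segs a [segment_set()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `load_segments` returns a [segment_set()].
#' @export
save_segments <- function(segs, path) {
  stopifnot(inherits(segs, "segment_set"))
  utils::write.table(format(segs$segments, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs_hz = segs$fs, align_index = segs$align_index - 1L,
               window_ms = segs$window_ms)
  if (!is.null(segs$source_times)) meta$source_times_s <- segs$source_times
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  segment_set(m, as.numeric(meta$fs_hz), meta$align_index + 1L,
              as.numeric(meta$window_ms),
              source_times = meta$source_times_s)
}

#' Read a filter specification from a JSON config
#'
#' The config mirrors [filter_spec()]: fields `phase_class`, `family`,
#' `order`, `band` (two numbers) and `fs`.
#'
#' @param path JSON file path.
#' @return A [filter_spec()].
#' @export
load_filter_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_spec(cfg$phase_class, cfg$family, cfg$order, cfg$band, cfg$fs)
}
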