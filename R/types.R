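# Domain containers shared by every module. Plain S3: a list with a class
# attribute and a validator, in the style of base-R time-series containers.

#' Continuous single-channel voltage trace
#'
#' @param samples numeric vector of voltages (arbitrary microvolt-like units).
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds (default 0).
#' @return An object of class `continuous_signal` with fields `samples`,
#'   `fs`, `t0`.
#' @examples
#' sig <- continuous_signal(sin(2 * pi * 50 * (0:999) / 1e3), fs = 1e3)
#' length(sig$samples)
#' @export
continuous_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %d samples @ %g Hz (%.4f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Spike times in seconds
#'
#' @param times numeric vector of strictly increasing spike times (s).
#' @param duration recording length in seconds.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  if (duration <= 0) stop("duration must be positive")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (rate %.2f Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Fixed-length spike waveform template
#'
#' Peak absolute amplitude is normalized to 1; `align_index` (1-based) marks
#' the dominant extremum used to align the template on spike times.
#'
#' @param samples numeric template samples.
#' @param fs sampling rate (Hz).
#' @param align_index 1-based index of the alignment extremum.
#' @param width_hh full width at half height of the dominant lobe (ms).
#' @return Object of class `waveform_template`.
#' @export
waveform_template <- function(samples, fs, align_index, width_hh) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) stop("template must have at least 3 samples")
  if (align_index < 1L || align_index > length(samples))
    stop("align_index out of bounds")
  pk <- max(abs(samples))
  if (abs(pk - 1) > 1e-9)
    stop("template peak |amplitude| must be normalized to 1")
  structure(list(samples = samples, fs = fs,
                 align_index = as.integer(align_index),
                 width_hh = width_hh),
            class = "waveform_template")
}

#' Spike-triggered mean waveform with per-sample spread
#'
#' @param mean per-sample mean shape.
#' @param std per-sample standard deviation (same length as `mean`).
#' @param n_spikes number of snippets averaged.
#' @param fs sampling rate (Hz).
#' @param window numeric `c(pre_ms, post_ms)` relative to the alignment point.
#' @return Object of class `mean_waveform`.
#' @export
new_mean_waveform <- function(mean, std, n_spikes, fs, window) {
  if (length(mean) != length(std)) stop("mean and std must match in length")
  if (n_spikes < 1L) stop("n_spikes must be >= 1")
  structure(list(mean = as.numeric(mean), std = as.numeric(std),
                 n_spikes = as.integer(n_spikes), fs = fs,
                 window = as.numeric(window)),
            class = "mean_waveform")
}

#' @export
print.mean_waveform <- function(x, ...) {
  cat(sprintf(
    "<mean_waveform> %d samples, n = %d spikes, window -%g/+%g ms @ %g Hz\n",
    length(x$mean), x$n_spikes, x$window[1L], x$window[2L], x$fs))
  invisible(x)
}

#' Set of equal-length threshold-crossing snippets
#'
#' @param segments numeric matrix, one snippet per row.
#' @param fs sampling rate (Hz).
#' @param align_index 1-based sample index of the threshold-crossing
#'   alignment within each snippet.
#' @param window_ms snippet width in milliseconds; must round to the snippet
#'   length at `fs`.
#' @param source_times optional snippet times in seconds.
#' @return Object of class `segment_set`.
#' @export
segment_set <- function(segments, fs, align_index, window_ms,
                        source_times = NULL) {
  segments <- as.matrix(segments)
  if (round(window_ms * fs / 1000) != ncol(segments))
    stop("window_ms inconsistent with snippet length at fs")
  if (align_index < 1L || align_index > ncol(segments))
    stop("align_index out of bounds")
  structure(list(segments = segments, fs = fs,
                 align_index = as.integer(align_index),
                 window_ms = window_ms, source_times = source_times),
            class = "segment_set")
}

#' Detection error probabilities at one threshold
#'
#' @param alpha false-positive probability in \[0, 1\].
#' @param beta false-negative probability in \[0, 1\].
#' @param threshold detection threshold used.
#' @return Object of class `detection_score`.
#' @export
detection_score <- function(alpha, beta, threshold) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, threshold = threshold),
            class = "detection_score")
}

#' ROC curve of threshold-crossing detection
#'
#' Points are (P(alpha), P(1 - beta)) pairs sorted by P(alpha).
#'
#' @param alpha false-positive probabilities.
#' @param tpr detection probabilities P(1 - beta).
#' @param thresholds matching thresholds (NA for appended anchors).
#' @return Object of class `roc_curve` with fields `alpha`, `tpr`,
#'   `thresholds`.
#' @export
roc_curve <- function(alpha, tpr, thresholds) {
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12) ||
      any(tpr < -1e-12 | tpr > 1 + 1e-12))
    stop("ROC coordinates must lie in [0, 1]")
  o <- order(alpha, tpr)
  structure(list(alpha = pmin(pmax(alpha[o], 0), 1),
                 tpr = pmin(pmax(tpr[o], 0), 1),
                 thresholds = thresholds[o]),
            class = "roc_curve")
}
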