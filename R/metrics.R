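# Waveform extraction and the distortion metrics: spike-triggered mean
# waveforms, normalized Euclidean distance between mean waveforms, the
# peak-over-noise SNR, and the low-order DFT sinusoid reconstruction of a
# mean waveform.

#' Spike-triggered mean waveform
#'
#' Averages fixed windows of the signal around each spike time (rounded to
#' the sample grid). The default window is 0.5 ms before to 1.5 ms after
#' the alignment point: 88 samples at 44 kHz, with the trough at 25% of
#' the window so delayed, rightward-smeared distorted shapes stay
#' in-window. Spikes whose window exceeds the signal bounds are dropped
#' with a warning.
#'
#' @param signal a [continuous_signal()].
#' @param train a [spike_train()] of alignment times (shared timestamps:
#'   apply the same train to raw and filtered versions of a signal).
#' @param window_ms numeric `c(pre_ms, post_ms)`.
#' @return A `mean_waveform` object.
#' @export
mean_waveform <- function(signal, train, window_ms = c(0.5, 1.5)) {
  stopifnot(inherits(signal, "continuous_signal"),
            inherits(train, "spike_train"))
  if (length(train$times) < 1L) stop("spike train is empty")
  fs <- signal$fs
  n <- length(signal$samples)
  pre_n <- round(window_ms[1L] * fs / 1000)
  post_n <- round(window_ms[2L] * fs / 1000)
  idx <- round((train$times - signal$t0) * fs) + 1L
  ok <- idx - pre_n >= 1L & idx + post_n - 1L <= n
  if (!all(ok)) {
    warning(sum(!ok), " spike(s) dropped: window exceeds signal bounds")
    idx <- idx[ok]
  }
  if (!length(idx)) stop("all spikes dropped: no window fits the signal")
  offs <- (-pre_n):(post_n - 1L)
  snip <- matrix(signal$samples[rep(idx, each = length(offs)) +
                                  rep(offs, times = length(idx))],
                 nrow = length(idx), byrow = TRUE)
  mu <- colMeans(snip)
  sdv <- if (nrow(snip) > 1L) apply(snip, 2L, stats::sd) else numeric(ncol(snip))
  new_mean_waveform(mu, sdv, nrow(snip), fs, window_ms)
}

as_waveform_samples <- function(w) {
  if (inherits(w, "mean_waveform")) w$mean
  else if (inherits(w, "waveform_template")) w$samples
  else as.numeric(w)
}

#' Normalized Euclidean distance between waveforms
#'
#' `D = ||test - ref||_2 / ||ref||_2`, computed sample-by-sample on
#' waveforms extracted with shared spike timestamps (no re-alignment).
#'
#' @param w_ref,w_test `mean_waveform` objects or numeric vectors of equal
#'   length; `w_ref` must have non-zero norm.
#' @return Non-negative scalar; 0 for identical shapes.
#' @export
normalized_distance <- function(w_ref, w_test) {
  a <- as_waveform_samples(w_ref)
  b <- as_waveform_samples(w_test)
  if (length(a) != length(b)) stop("waveforms must have equal length")
  na <- sqrt(sum(a^2))
  if (na == 0) stop("reference waveform has zero norm")
  sqrt(sum((b - a)^2)) / na
}

#' Peak-over-noise SNR of a waveform
#'
#' Ratio of the maximum absolute amplitude of the (mean) waveform to the
#' background-noise standard deviation.
#'
#' @param waveform `mean_waveform` or numeric vector.
#' @param noise_std positive noise standard deviation.
#' @return Non-negative scalar.
#' @export
snr_of <- function(waveform, noise_std) {
  if (!is.numeric(noise_std) || noise_std <= 0)
    stop("noise_std must be positive")
  max(abs(as_waveform_samples(waveform))) / noise_std
}

#' Robust background-noise SD from spike-free samples
#'
#' Median absolute deviation (x 1.4826) of the samples at least `guard_ms`
#' away from every spike.
#'
#' @param signal a [continuous_signal()].
#' @param train a [spike_train()].
#' @param guard_ms half-width of the exclusion zone around each spike (ms).
#' @return Estimated noise SD.
#' @export
estimate_noise_std <- function(signal, train, guard_ms = 2) {
  fs <- signal$fs
  n <- length(signal$samples)
  keep <- rep(TRUE, n)
  g <- round(guard_ms * fs / 1000)
  for (t in train$times) {
    i <- round((t - signal$t0) * fs) + 1L
    keep[max(1L, i - g):min(n, i + g)] <- FALSE
  }
  if (!any(keep)) stop("no spike-free samples remain")
  stats::mad(signal$samples[keep], center = stats::median(signal$samples[keep]))
}

#' Low-order DFT sinusoid reconstruction of a waveform
#'
#' Decomposes the waveform with a DFT and re-synthesizes it as the sum of
#' the first `n_components` sinusoids (DC excluded), each with the
#' DFT-derived amplitude and phase. For an 88-sample 2 ms window the
#' first 8 components cover 0.5-4 kHz.
#'
#' @param waveform `mean_waveform` or numeric vector of length N.
#' @param n_components number of sinusoids, between 1 and `floor(N/2)`.
#' @return Numeric reconstruction of length N (zero mean).
#' @export
dft_reconstruct <- function(waveform, n_components = 8L) {
  x <- as_waveform_samples(waveform)
  N <- length(x)
  if (n_components < 1L || n_components > N %/% 2L)
    stop("n_components must lie in [1, floor(N/2)]")
  X <- stats::fft(x)
  n <- 0:(N - 1L)
  rec <- numeric(N)
  for (k in seq_len(n_components)) {
    amp <- Mod(X[k + 1L]) / N
    ph <- Arg(X[k + 1L])
    fac <- if (N %% 2L == 0L && k == N %/% 2L) 1 else 2
    rec <- rec + fac * amp * cos(2 * pi * k * n / N + ph)
  }
  rec
}
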