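# Welch power spectral density estimate, used to verify the 1/f noise
# spectrum. Hann-windowed segments with 50% overlap, averaged
# periodograms, one-sided.

#' Welch PSD estimate
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nfft segment length (power of two recommended).
#' @return List with `freq` (Hz, excluding DC) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nfft = 8192L) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than one Welch segment")
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1L)) / (nfft - 1L))
  wnorm <- sum(win^2)
  starts <- seq(1L, n - nfft + 1L, by = nfft %/% 2L)
  acc <- numeric(nfft %/% 2L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[2:(nfft %/% 2L + 1L)])^2) / (wnorm * fs)
  }
  p <- 2 * acc / length(starts)   # one-sided
  list(freq = (1:(nfft %/% 2L)) * fs / nfft, psd = p)
}

#' Log-log spectral slope over a frequency band
#'
#' Least-squares slope of log10(PSD) against log10(f); -1 for pink noise.
#'
#' @param freq,psd PSD estimate as from [welch_psd()].
#' @param band numeric `c(lo, hi)` in Hz.
#' @return The fitted slope.
#' @export
psd_loglog_slope <- function(freq, psd, band = c(10, NA)) {
  keep <- freq >= band[1L] & (is.na(band[2L]) | freq <= band[2L]) & psd > 0
  lf <- log10(freq[keep])
  lp <- log10(psd[keep])
  unname(stats::coef(stats::lm(lp ~ lf))[2L])
}
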