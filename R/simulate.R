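# Ground-truth signal synthesis: a homogeneous Poisson spike train with an
# absolute refractory period, convolved with a biphasic spike template (the
# analytic derivative of a smooth action-potential surrogate) and summed
# with pink (1/f) noise scaled to a target SNR, where SNR is the template
# peak amplitude over the noise standard deviation.

#' Simulation configuration
#'
#' @param rate firing rate (Hz), the rate of the exponential inter-spike
#'   intervals beyond the dead time.
#' @param duration recording length (s).
#' @param refractory_ms absolute refractory period (ms); default 1.
#' @param width_hh_ms template full width at half height (ms).
#' @param target_snr desired SNR, template peak over noise SD. `Inf` gives
#'   a noise-free signal.
#' @param fs sampling rate (Hz); default 44000 (an 88-sample, 2 ms
#'   waveform window).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(rate = 10, duration = 10, refractory_ms = 1,
                       width_hh_ms = 0.4, target_snr = 2.7, fs = 44000,
                       seed = 1L) {
  if (rate < 0) stop("rate must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  if (refractory_ms <= 0) stop("refractory_ms must be positive")
  if (target_snr <= 0) stop("target_snr must be positive")
  structure(list(rate = rate, duration = duration,
                 refractory_ms = refractory_ms,
                 width_hh_ms = width_hh_ms, target_snr = target_snr,
                 fs = fs, seed = as.integer(seed)),
            class = "sim_config")
}

#' Poisson spike train with an absolute refractory period
#'
#' Inter-spike intervals are `refractory_ms/1000 + rexp(1/rate)`: a dead
#' time followed by an exponential tail, so the expected spike count is
#' `duration * rate / (1 + rate * refractory)`.
#'
#' @param rate firing rate of the exponential part (Hz).
#' @param duration recording length (s).
#' @param refractory_ms dead time (ms).
#' @param seed optional integer seed (set for reproducibility).
#' @return A [spike_train()].
#' @export
generate_spike_train <- function(rate, duration, refractory_ms = 1,
                                 seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(spike_train(numeric(0), duration))
  tref <- refractory_ms / 1000
  times <- numeric(0)
  t_last <- NULL
  repeat {
    n_draw <- max(100L, ceiling(1.5 * rate * duration))
    isi <- stats::rexp(n_draw, rate)
    if (is.null(t_last)) {
      # first arrival has no preceding spike, hence no dead time
      new <- cumsum(c(isi[1L], isi[-1L] + tref))
    } else {
      new <- t_last + cumsum(isi + tref)
    }
    times <- c(times, new)
    if (times[length(times)] > duration) break
    t_last <- times[length(times)]
  }
  spike_train(times[times <= duration], duration)
}

# Smooth action-potential surrogate: a positive Gaussian depolarization
# with a shallower, wider after-phase. Its analytic time derivative is the
# biphasic extracellular-like template (dominant negative trough).
ap_surrogate_deriv <- function(u) {
  # g(u) = exp(-u^2/2) - 0.3 exp(-(u - 2)^2/8)   (s1 = 1, s2 = 2, d = 2)
  -u * exp(-u^2 / 2) + 0.3 * (u - 2) / 4 * exp(-(u - 2)^2 / 8)
}

# FWHM (in u-units) of the dominant lobe of f on a dense grid, by linear
# interpolation of the half-height crossings.
lobe_fwhm <- function(u, y) {
  i0 <- which.max(abs(y))
  s <- sign(y[i0])
  yy <- s * y
  half <- yy[i0] / 2
  il <- i0
  while (il > 1L && yy[il - 1L] > half) il <- il - 1L
  ir <- i0
  while (ir < length(yy) && yy[ir + 1L] > half) ir <- ir + 1L
  if (il == 1L || ir == length(yy)) stop("half-height crossing not found")
  ul <- u[il - 1L] + (half - yy[il - 1L]) / (yy[il] - yy[il - 1L]) *
    (u[il] - u[il - 1L])
  ur <- u[ir] + (half - yy[ir]) / (yy[ir + 1L] - yy[ir]) *
    (u[ir + 1L] - u[ir])
  ur - ul
}

#' Spike waveform template of controlled width
#'
#' The template is the analytic derivative of a double-Gaussian action
#' potential surrogate, time-rescaled so the full width at half height of
#' its dominant (negative) lobe equals `width_hh_ms`, sampled at `fs`, and
#' normalized to peak absolute amplitude 1. The shape decays below 1% of
#' the peak at both ends.
#'
#' @param width_hh_ms target half-height width (ms).
#' @param fs sampling rate (Hz).
#' @return A [waveform_template()].
#' @examples
#' tpl <- make_template(0.4, 44000)
#' measure_width_hh(tpl$samples, tpl$fs)  # ~ 0.4 ms
#' @export
make_template <- function(width_hh_ms, fs) {
  if (width_hh_ms <= 0) stop("width_hh_ms must be positive")
  # dominant-lobe width of the unscaled shape, computed once on a fine grid
  ug <- seq(-5, 9, length.out = 20001L)
  w0 <- lobe_fwhm(ug, ap_surrogate_deriv(ug))
  scl <- (width_hh_ms / 1000) / w0        # seconds per u-unit
  dt <- 1 / fs
  u <- seq(-5, 9, by = dt / scl)
  if (length(u) < 5L)
    stop("width_hh_ms too small for this sampling rate (template < 5 samples)")
  y <- ap_surrogate_deriv(u)
  y <- y / max(abs(y))
  waveform_template(y, fs, which.min(y), width_hh_ms)
}

#' Measure the half-height width of a sampled waveform
#'
#' Full width at half height of the dominant extremum, with linear
#' interpolation between samples.
#'
#' @param x numeric waveform samples.
#' @param fs sampling rate (Hz).
#' @return Width in milliseconds.
#' @export
measure_width_hh <- function(x, fs) {
  lobe_fwhm(seq_along(x) / fs, x) * 1000
}

#' Seedable pink (1/f) noise
#'
#' Spectral-shaping synthesis: a white Gaussian sequence is transformed,
#' its spectrum multiplied by an `f^(-1/2)` amplitude mask (DC zeroed),
#' transformed back and standardized to zero mean and unit variance. The
#' power spectral density is then proportional to 1/f.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate (Hz), used only for frequency bookkeeping.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_pink_noise <- function(n_samples, fs = 44000, seed = NULL) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n_samples)
  W <- stats::fft(w)
  k <- seq_len(n_samples) - 1L
  f <- pmin(k, n_samples - k) * fs / n_samples  # two-sided bin frequencies
  mask <- numeric(n_samples)
  mask[f > 0] <- 1 / sqrt(f[f > 0])
  x <- Re(stats::fft(W * mask, inverse = TRUE)) / n_samples
  as.numeric(scale(x))
}

#' Assemble a simulated extracellular spiking signal
#'
#' The spike train is placed as a delta train at integer sample positions
#' and convolved with the template (the template's alignment trough lands
#' exactly on each spike sample); pink noise scaled to
#' `sigma = peak / target_snr = 1 / target_snr` is added. Spikes whose
#' template support would overflow the signal are dropped; the returned
#' train holds the sample-grid times actually placed.
#'
#' @param config a [sim_config()].
#' @return List with elements `signal` ([continuous_signal()]),
#'   `train` ([spike_train()]), `template` ([waveform_template()]) and
#'   `noise_sd` (the sigma actually applied).
#' @export
assemble_signal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n <- round(config$duration * fs)
  tpl <- make_template(config$width_hh_ms, fs)
  if (length(tpl$samples) > n)
    stop("duration too short to hold one template")
  set.seed(config$seed)
  train <- generate_spike_train(config$rate, config$duration,
                                config$refractory_ms, seed = NULL)
  idx <- round(train$times * fs) + 1L
  lead <- tpl$align_index - 1L
  trail <- length(tpl$samples) - tpl$align_index
  keep <- idx - lead >= 1L & idx + trail <= n
  idx <- idx[keep]
  x <- numeric(n)
  for (i in idx) {
    rng <- (i - lead):(i + trail)
    x[rng] <- x[rng] + tpl$samples
  }
  sigma <- if (is.infinite(config$target_snr)) 0 else 1 / config$target_snr
  if (sigma > 0) x <- x + sigma * generate_pink_noise(n, fs, seed = NULL)
  list(signal = continuous_signal(x, fs),
       train = spike_train((idx - 1L) / fs, config$duration),
       template = tpl,
       noise_sd = sigma)
}
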