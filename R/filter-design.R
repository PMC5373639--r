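# Filter design: causal Butterworth band-pass realized as cascaded biquads
# (second-order sections) via the analog prototype -> band-pass transform ->
# bilinear transform route, and a linear-phase Hamming-window FIR band-pass.
# Direct-form coefficients of a 300 Hz edge at 44 kHz are numerically
# fragile, hence the cascaded form.

#' Declarative filter description
#'
#' @param phase_class one of `"NLP"` (causal, nonlinear phase), `"ZP"`
#'   (zero phase: the same causal filter run forward and backward) or
#'   `"LP"` (linear phase, symmetric FIR). ZP is only defined for
#'   recursive families.
#' @param family `"butterworth"` or `"fir_hamming"`.
#' @param order filter order. For the Butterworth band-pass this is the
#'   number of poles (must be even: a 4-pole band-pass uses a 2nd-order
#'   low-pass prototype); for the FIR it is the number of taps minus one.
#' @param band numeric `c(low_hz, high_hz)` pass-band edges.
#' @param fs sampling rate (Hz).
#' @return Object of class `filter_spec`.
#' @examples
#' filter_spec("NLP", "butterworth", 4, c(300, 6000), fs = 44000)
#' @export
filter_spec <- function(phase_class = c("NLP", "ZP", "LP"),
                        family = c("butterworth", "fir_hamming"),
                        order, band, fs) {
  phase_class <- match.arg(phase_class)
  family <- match.arg(family)
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stop("band must be c(low_hz, high_hz) with 0 < low < high")
  if (band[2L] >= fs / 2) stop("high band edge must be below Nyquist")
  if (order < 1L) stop("order must be >= 1")
  if (family == "butterworth" && order %% 2L != 0L)
    stop("band-pass Butterworth order (pole count) must be even")
  if (phase_class == "ZP" && family != "butterworth")
    stop("ZP is defined only for recursive families")
  if (phase_class == "LP" && family != "fir_hamming")
    stop("LP here denotes the symmetric FIR family")
  structure(list(phase_class = phase_class, family = family,
                 order = as.integer(order), band = as.numeric(band),
                 fs = fs),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s %s order %d, band %g-%g Hz @ %g Hz\n",
              x$phase_class, x$family, x$order, x$band[1L], x$band[2L],
              x$fs))
  invisible(x)
}

# Butterworth low-pass prototype poles (unit cutoff, all-pole, gain 1)
butter_prototype_poles <- function(m) {
  k <- seq_len(m)
  exp(1i * pi * (2 * k + m - 1) / (2 * m))
}

# Analog band-pass zpk from the prototype: s <- (s^2 + w0^2) / (bw * s)
analog_bandpass_zpk <- function(m, w1, w2) {
  bw <- w2 - w1
  w0sq <- w1 * w2
  p <- butter_prototype_poles(m)
  poles <- c(vapply(p, function(pk) {
    disc <- sqrt((pk * bw)^2 / 4 - w0sq + 0i)
    pk * bw / 2 + disc
  }, complex(1)),
  vapply(p, function(pk) {
    disc <- sqrt((pk * bw)^2 / 4 - w0sq + 0i)
    pk * bw / 2 - disc
  }, complex(1)))
  list(zeros = rep(0 + 0i, m), poles = poles, gain = bw^m)
}

# Bilinear transform of an analog zpk at sampling rate fs (with the caller
# responsible for pre-warping the analog edges).
bilinear_zpk <- function(zeros, poles, gain, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  # pole excess maps extra zeros to z = -1
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  kd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  list(zeros = zd, poles = pd, gain = kd)
}

# Pair the band-pass digital zpk into biquad sections: each section takes a
# conjugate pole pair plus one zero at z = +1 and one at z = -1, so every
# section is itself a band-pass. Returns an n_sections x 6 matrix with
# columns b0 b1 b2 a0 a1 a2.
bandpass_zpk_to_sos <- function(zpk) {
  p <- zpk$poles
  pu <- p[Im(p) > 0]
  if (2L * length(pu) != length(p))
    stop("expected complex-conjugate pole pairs")
  pu <- pu[order(-Mod(pu))]  # poles nearest the unit circle first
  ns <- length(pu)
  sos <- matrix(0, ns, 6L)
  for (i in seq_len(ns)) {
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(pu[i]), Mod(pu[i])^2)
  }
  sos[1L, 1:3] <- sos[1L, 1:3] * zpk$gain
  sos
}

#' Realize a filter specification as coefficients
#'
#' Butterworth band-pass filters are designed with pre-warped bilinear
#' transformation so the magnitude response is exactly 1/sqrt(2) at the
#' requested band edges, and returned as cascaded second-order sections.
#' FIR filters are Hamming-windowed ideal band-pass taps, scaled to unit
#' gain at the arithmetic band centre; the taps are exactly symmetric,
#' hence linear phase with group delay `order/2` samples.
#'
#' @param spec a [filter_spec()].
#' @return Object of class `filter_realization` with either `sos`
#'   (matrix of second-order sections, columns b0 b1 b2 a0 a1 a2) or
#'   `taps` (FIR coefficients), and the originating `spec`.
#' @examples
#' fr <- design_filter(filter_spec("NLP", "butterworth", 4, c(300, 6000),
#'                                 fs = 44000))
#' Mod(freq_response(fr, 300))  # ~ 1/sqrt(2)
#' @export
design_filter <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- spec$fs
  if (spec$family == "butterworth") {
    m <- spec$order %/% 2L
    # pre-warp band edges
    w1 <- 2 * fs * tan(pi * spec$band[1L] / fs)
    w2 <- 2 * fs * tan(pi * spec$band[2L] / fs)
    zpk <- analog_bandpass_zpk(m, w1, w2)
    zpkd <- bilinear_zpk(zpk$zeros, zpk$poles, zpk$gain, fs)
    if (any(Mod(zpkd$poles) >= 1))
      stop("designed filter is unstable")
    out <- structure(list(sos = bandpass_zpk_to_sos(zpkd),
                          poles = zpkd$poles, taps = NULL, spec = spec),
                     class = "filter_realization")
  } else {
    n <- spec$order
    m <- n / 2
    k <- 0:n
    w1 <- 2 * pi * spec$band[1L] / fs
    w2 <- 2 * pi * spec$band[2L] / fs
    d <- k - m
    h <- ifelse(d == 0, (w2 - w1) / pi,
                (sin(w2 * d) - sin(w1 * d)) / (pi * d))
    win <- 0.54 - 0.46 * cos(2 * pi * k / n)
    win <- (win + rev(win)) / 2  # exact tap symmetry down to the last ulp
    h <- h * win
    # unit gain at the arithmetic band centre
    wc <- (w1 + w2) / 2
    h <- h / sum(h * cos(wc * d))
    out <- structure(list(sos = NULL, poles = complex(0), taps = h,
                          spec = spec),
                     class = "filter_realization")
  }
  out
}

#' @export
print.filter_realization <- function(x, ...) {
  print(x$spec)
  if (!is.null(x$sos))
    cat(sprintf("  %d second-order sections, max |pole| = %.6f\n",
                nrow(x$sos), max(Mod(x$poles))))
  else
    cat(sprintf("  %d FIR taps (symmetric)\n", length(x$taps)))
  invisible(x)
}

is_recursive <- function(filt) !is.null(filt$sos)

#' Complex frequency response of a realized filter
#'
#' Evaluates H(e^(i 2 pi f / fs)) of the causal realization. For a
#' zero-phase specification the returned response is |H|^2 (real and
#' non-negative): the net effect of the forward-backward pass.
#'
#' @param filt a `filter_realization`.
#' @param freqs frequencies in Hz, within (0, fs/2).
#' @return Complex vector of responses.
#' @export
freq_response <- function(filt, freqs) {
  fs <- filt$spec$fs
  if (any(freqs < 0 | freqs > fs / 2)) stop("freqs must lie in [0, fs/2]")
  z <- exp(-1i * 2 * pi * freqs / fs)
  if (is_recursive(filt)) {
    h <- rep(1 + 0i, length(freqs))
    for (i in seq_len(nrow(filt$sos))) {
      s <- filt$sos[i, ]
      h <- h * (s[1L] + s[2L] * z + s[3L] * z^2) /
        (s[4L] + s[5L] * z + s[6L] * z^2)
    }
  } else {
    h <- vapply(z, function(zz) sum(filt$taps * zz^(seq_along(filt$taps) - 1)),
                complex(1))
  }
  if (filt$spec$phase_class == "ZP") h <- Mod(h)^2 + 0i
  h
}

unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

#' Unwrapped phase response
#'
#' The phase is evaluated on a dense grid up to Nyquist (at least 4096
#' points, plus the requested frequencies), unwrapped by removing 2 pi
#' jumps, anchored near 0 Hz, and returned at the requested frequencies.
#' A zero-phase realization reports identically zero phase.
#'
#' @inheritParams freq_response
#' @param n_grid minimum dense-grid size used for unwrapping.
#' @return Numeric vector of unwrapped phase in radians.
#' @export
phase_response <- function(filt, freqs, n_grid = 8192L) {
  fs <- filt$spec$fs
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("freqs must lie strictly inside (0, fs/2)")
  if (filt$spec$phase_class == "ZP") return(rep(0, length(freqs)))
  grid <- sort(unique(c(seq(fs / 2 / n_grid, fs / 2 * (1 - 1e-9),
                            length.out = n_grid), freqs)))
  phi <- unwrap_phase(Arg(freq_response(filt, grid)))
  phi[match(freqs, grid)]
}

#' Group delay in samples
#'
#' Numerical negative derivative of the unwrapped phase with respect to
#' angular frequency (radians/sample), by central differences.
#'
#' @inheritParams freq_response
#' @param df half-width of the central difference (Hz).
#' @return Numeric vector of delays in samples.
#' @export
group_delay <- function(filt, freqs, df = 0.25) {
  fs <- filt$spec$fs
  if (filt$spec$phase_class == "ZP") return(rep(0, length(freqs)))
  vapply(freqs, function(f) {
    lo <- max(f - df, 1e-6)
    hi <- min(f + df, fs / 2 * (1 - 1e-9))
    h <- freq_response(filt, c(lo, hi))
    dphi <- Arg(h[2L] / h[1L])  # local unwrap: |dphi| << pi for small df
    -dphi / (2 * pi * (hi - lo) / fs)
  }, numeric(1))
}
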