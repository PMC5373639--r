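# Filter application. The causal path runs each biquad with stats::filter
# (C implementation): the moving-average part as a one-sided convolution,
# the autoregressive part as a recursive filter, both with zero initial
# conditions. Zero-phase filtering is the forward-backward application of
# the causal filter over an odd-reflection-padded signal.

# One biquad (or FIR tap vector) applied causally with zero initial state.
causal_ba <- function(x, b, a = 1) {
  n <- length(x)
  nb <- length(b)
  if (nb > 1L) {
    xp <- c(rep(0, nb - 1L), x)
    v <- stats::filter(xp, b, method = "convolution", sides = 1L)
    v <- as.numeric(v)[nb:(nb + n - 1L)]
  } else {
    v <- b * x
  }
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

sos_filter <- function(x, sos) {
  for (i in seq_len(nrow(sos))) {
    x <- causal_ba(x, sos[i, 1:3], sos[i, 4:6])
  }
  x
}

#' Apply a filter causally
#'
#' Strictly causal application with zero initial conditions: the output
#' before the first non-zero input sample is identically zero, and length
#' is preserved. This is the online (nonlinear-phase or linear-phase)
#' filtration path.
#'
#' @param signal a [continuous_signal()].
#' @param filt a `filter_realization` from [design_filter()].
#' @return A filtered [continuous_signal()].
#' @export
apply_causal <- function(signal, filt) {
  stopifnot(inherits(signal, "continuous_signal"),
            inherits(filt, "filter_realization"))
  if (abs(signal$fs - filt$spec$fs) > 1e-9)
    stop("sampling rate mismatch between signal and filter spec")
  y <- if (is_recursive(filt)) sos_filter(signal$samples, filt$sos)
       else causal_ba(signal$samples, filt$taps)
  continuous_signal(y, signal$fs, signal$t0)
}

# Default padding length for the forward-backward pass: grows with the
# number of sections; generous relative to the biquad transient scale.
default_pad <- function(filt) 3L * (4L * nrow(filt$sos) + 1L)

odd_reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad <= 0L) return(x)
  if (pad > n - 1L) stop("signal too short for the requested edge padding")
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  c(left, x, right)
}

#' Apply a recursive filter with zero net phase
#'
#' Forward pass, time reversal, second pass, re-reversal: the phase
#' responses cancel and the magnitude response is squared. Edges are
#' handled by odd-symmetric reflection padding (removed after filtering),
#' which suppresses the start/end transients of the two passes.
#'
#' @inheritParams apply_causal
#' @param pad padding length per side in samples; default
#'   `3 * (4 * n_sections + 1)`.
#' @return A filtered [continuous_signal()].
#' @export
apply_zero_phase <- function(signal, filt, pad = NULL) {
  stopifnot(inherits(signal, "continuous_signal"),
            inherits(filt, "filter_realization"))
  if (!is_recursive(filt))
    stop("zero-phase application is defined for recursive filters only")
  if (abs(signal$fs - filt$spec$fs) > 1e-9)
    stop("sampling rate mismatch between signal and filter spec")
  if (is.null(pad)) pad <- default_pad(filt)
  xp <- odd_reflect_pad(signal$samples, pad)
  y <- sos_filter(xp, filt$sos)
  y <- rev(sos_filter(rev(y), filt$sos))
  if (pad > 0L) y <- y[(pad + 1L):(pad + length(signal$samples))]
  continuous_signal(y, signal$fs, signal$t0)
}

#' Apply a filter according to its phase class
#'
#' Dispatches to [apply_causal()] for NLP/LP specifications and to
#' [apply_zero_phase()] for ZP ones.
#'
#' @inheritParams apply_causal
#' @return A filtered [continuous_signal()].
#' @export
apply_filter <- function(signal, filt) {
  if (filt$spec$phase_class == "ZP") apply_zero_phase(signal, filt)
  else apply_causal(signal, filt)
}
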