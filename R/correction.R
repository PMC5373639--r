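# Phase-distortion correction by reversed refiltering: time-reverse the
# causally filtered signal, run the same causal filter again, reverse
# back. The phase response cancels (zero net phase) and the magnitude
# response is squared, so the corrected signal matches the zero-phase
# filtered raw signal. For threshold-crossing segments the snippet is
# first expanded past its boundaries to approximate the missing samples.

#' Correct a causally filtered continuous signal
#'
#' Requires full knowledge of the nonlinear-phase filter that produced the
#' distortion. The output is timestamp-aligned with the original raw
#' signal and equals its zero-phase filtration away from the edges.
#'
#' @param distorted the causally filtered [continuous_signal()].
#' @param filt the same `filter_realization` that was applied.
#' @return A corrected [continuous_signal()].
#' @export
correct_continuous <- function(distorted, filt) {
  stopifnot(inherits(distorted, "continuous_signal"),
            inherits(filt, "filter_realization"))
  if (!is_recursive(filt))
    stop("reversed refiltering requires the recursive (NLP) realization")
  if (max(Mod(filt$poles)) >= 1) stop("filter is unstable")
  y <- rev(sos_filter(rev(distorted$samples), filt$sos))
  continuous_signal(y, distorted$fs, distorted$t0)
}

# Edge transient length: samples until the slowest pole decays to `tol`.
transient_samples <- function(filt, tol = 1e-12) {
  r <- max(Mod(filt$poles))
  as.integer(ceiling(log(tol) / log(r)))
}

#' Expand a segment past its boundaries
#'
#' Boundary-expansion strategies for segmented waveforms: `zeros` pads
#' with zeros; `constant` repeats the edge value; `linear` continues the
#' straight line through the two outermost samples of each side; `mirror`
#' reflects the segment without repeating the edge sample.
#'
#' @param segment numeric snippet (length >= 2; >= 3 for `linear`).
#' @param mode one of `"zeros"`, `"constant"`, `"linear"`, `"mirror"`.
#' @param pad_n expansion length per side, in samples.
#' @return Numeric vector of length `length(segment) + 2 * pad_n`.
#' @examples
#' expand_segment(c(0, 1, 2), "linear", 3)  # right extension 3, 4, 5
#' @export
expand_segment <- function(segment,
                           mode = c("zeros", "constant", "linear", "mirror"),
                           pad_n) {
  mode <- match.arg(mode)
  if (pad_n < 0) stop("pad_n must be non-negative")
  if (pad_n == 0) return(segment)
  n <- length(segment)
  if (n < 2L || (mode == "linear" && n < 3L))
    stop("segment too short for this expansion mode")
  left <- switch(mode,
    zeros = rep(0, pad_n),
    constant = rep(segment[1L], pad_n),
    linear = segment[1L] - (segment[2L] - segment[1L]) * (pad_n:1),
    mirror = segment[pmin(n, pad_n + 1L):2L])
  right <- switch(mode,
    zeros = rep(0, pad_n),
    constant = rep(segment[n], pad_n),
    linear = segment[n] + (segment[n] - segment[n - 1L]) * (1:pad_n),
    mirror = segment[(n - 1L):max(1L, n - pad_n)])
  if (mode == "mirror" && pad_n > n - 1L)
    stop("mirror expansion longer than segment - 1")
  c(left, segment, right)
}

#' Correct one segmented waveform
#'
#' Expands the snippet, applies the reversed refiltering of
#' [correct_continuous()], and crops back to the original window.
#'
#' @param segment numeric snippet cut from an NLP-filtered stream.
#' @param filt the `filter_realization` that produced the distortion.
#' @param mode expansion mode, see [expand_segment()].
#' @param pad_ms expansion length per side (ms); default 0.5 ms, the
#'   edge-transient scale of the default 300 Hz band edge. Longer pads
#'   buy nothing once the filter transient is covered, and actively hurt
#'   the linear mode, whose extrapolated ramp ends in a discontinuity
#'   that grows with pad length.
#' @param fs sampling rate (Hz); defaults to the filter spec's rate.
#' @return Corrected numeric snippet, same length as `segment`.
#' @export
correct_segment <- function(segment, filt,
                            mode = c("zeros", "constant", "linear", "mirror"),
                            pad_ms = 0.5, fs = filt$spec$fs) {
  mode <- match.arg(mode)
  n <- length(segment)
  if (is.null(pad_ms)) pad_ms <- 0.5
  pad_n <- round(pad_ms * fs / 1000)
  if (mode == "mirror") pad_n <- min(pad_n, n - 1L)
  ext <- expand_segment(segment, mode, pad_n)
  cor <- correct_continuous(continuous_signal(ext, fs), filt)
  cor$samples[(pad_n + 1L):(pad_n + n)]
}

#' Correct every snippet of a segment set
#'
#' @param segs a [segment_set()].
#' @inheritParams correct_segment
#' @return A [segment_set()] of corrected snippets.
#' @export
correct_segments <- function(segs, filt,
                             mode = c("zeros", "constant", "linear", "mirror"),
                             pad_ms = 0.5) {
  stopifnot(inherits(segs, "segment_set"))
  mode <- match.arg(mode)
  out <- t(apply(segs$segments, 1L, correct_segment, filt = filt,
                 mode = mode, pad_ms = pad_ms, fs = segs$fs))
  segment_set(out, segs$fs, segs$align_index, segs$window_ms,
              segs$source_times)
}

#' Correction accuracy
#'
#' `max(0, 1 - D(reference, corrected))` with D the normalized Euclidean
#' distance. The natural reference is the zero-phase filtered waveform
#' over the same window (same squared-magnitude response as the corrected
#' signal); pass the raw waveform for a raw-reference variant.
#'
#' @param corrected,reference numeric waveforms (or `mean_waveform`s) of
#'   equal length.
#' @return Scalar in \[0, 1\]; 1 for perfect restoration.
#' @export
correction_accuracy <- function(corrected, reference) {
  max(0, 1 - normalized_distance(reference, corrected))
}

#' Parameter sweeps of distortion and correction
#'
#' Runs matched noise-free simulations over a one-dimensional grid and
#' reports, per grid point, seed and filter class, the normalized
#' distance of the filtered mean waveform from the raw one, the waveform
#' SNR numerator (peak amplitude), and — for segment sweeps — the
#' correction accuracy of each expansion mode (filled on NLP rows).
#'
#' @param vary one of `"width"` (template half-height width, ms),
#'   `"cutoff"` (band low edge, Hz) or `"segment"` (segment width, ms).
#' @param grid numeric grid of the varied parameter.
#' @param seeds integer seeds; one simulation per seed.
#' @param config base [sim_config()] (its `target_snr` may be `Inf`).
#' @param band,order band edges and order of the Butterworth filter when
#'   not the swept parameter.
#' @param segment_ms segment width used when `vary` is not `"segment"`
#'   but segment-correction accuracy is still wanted.
#' @param roi_ms accuracy is evaluated on this fixed region of interest
#'   around the alignment point (ms before/after), so segment widths are
#'   comparable; default the 2 ms waveform window.
#' @return A `data.frame`, one row per grid point x seed x filter class,
#'   with the waveform distance from raw, the waveform peak, and (on NLP
#'   rows) per-expansion-mode correction accuracy against the zero-phase
#'   reference (`accuracy_*`) and against the raw waveform
#'   (`accuracy_raw_*`).
#' @export
run_sweep <- function(vary = c("width", "cutoff", "segment"), grid,
                      seeds = 1L,
                      config = sim_config(duration = 4, target_snr = Inf),
                      band = c(300, 6000), order = 4L, segment_ms = 2,
                      roi_ms = c(0.5, 1.5)) {
  vary <- match.arg(vary)
  if (!length(grid)) stop("empty sweep grid")
  modes <- c("zeros", "constant", "linear", "mirror")
  acc_na <- setNames(rep(NA_real_, 8L),
                     c(paste0("accuracy_", modes),
                       paste0("accuracy_raw_", modes)))
  rows <- list()
  for (g in grid) for (sd in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    if (vary == "width") cfg$width_hh_ms <- g
    bnd <- if (vary == "cutoff") c(g, band[2L]) else band
    sim <- assemble_signal(cfg)
    nlp <- design_filter(filter_spec("NLP", "butterworth", order, bnd,
                                     cfg$fs))
    sig_nlp <- apply_causal(sim$signal, nlp)
    sig_zp <- apply_zero_phase(sim$signal, nlp)
    w_raw <- mean_waveform(sim$signal, sim$train)
    w_nlp <- mean_waveform(sig_nlp, sim$train)
    w_zp <- mean_waveform(sig_zp, sim$train)
    seg_ms <- if (vary == "segment") g else segment_ms
    # boundary truncation is the phenomenon under study: segments that
    # contain a neighbouring spike are a different failure mode and are
    # excluded from the accuracy average; the gap is tied to the largest
    # segment width so grid points share the same spike subset
    gap_s <- 1.5 * (if (vary == "segment") max(grid) else seg_ms) / 1000
    tr <- isolated_spikes(sim$train, gap_s)
    acc <- acc_na
    if (length(tr$times)) {
      seg <- cut_segments(sig_nlp, tr, seg_ms)
      ref_zp <- cut_segments(sig_zp, tr, seg_ms)
      ref_raw <- cut_segments(sim$signal, tr, seg_ms)
      fs <- cfg$fs
      take_roi <- function(row, align)
        row[(align - round(roi_ms[1L] * fs / 1000)):
              (align + round(roi_ms[2L] * fs / 1000) - 1L)]
      for (m in modes) {
        segc <- correct_segments(seg, nlp, m)
        av <- vapply(seq_len(nrow(segc$segments)), function(i) {
          cr <- take_roi(segc$segments[i, ], segc$align_index)
          c(correction_accuracy(cr, take_roi(ref_zp$segments[i, ],
                                             ref_zp$align_index)),
            correction_accuracy(cr, take_roi(ref_raw$segments[i, ],
                                             ref_raw$align_index)))
        }, numeric(2))
        acc[paste0("accuracy_", m)] <- mean(av[1L, ])
        acc[paste0("accuracy_raw_", m)] <- mean(av[2L, ])
      }
    }
    for (cl in c("NLP", "ZP")) {
      w <- if (cl == "NLP") w_nlp else w_zp
      rows[[length(rows) + 1L]] <- data.frame(
        vary = vary, value = g, seed = sd, phase_class = cl,
        distance = normalized_distance(w_raw, w),
        peak = max(abs(w$mean)),
        t(if (cl == "NLP") acc else acc_na))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only spikes with no neighbour within a gap
#'
#' @param train a [spike_train()].
#' @param gap_s minimum distance (s) to both neighbours.
#' @return A filtered [spike_train()].
#' @export
isolated_spikes <- function(train, gap_s) {
  t <- train$times
  ok <- c(Inf, diff(t)) > gap_s & c(diff(t), Inf) > gap_s
  spike_train(t[ok], train$duration)
}

#' Cut threshold-aligned segments around spike times
#'
#' Extracts `window_ms`-wide snippets centred so the alignment point sits
#' at 25% of the window (matching the mean-waveform convention).
#'
#' @param signal a [continuous_signal()].
#' @param train alignment times.
#' @param window_ms segment width (ms).
#' @return A [segment_set()].
#' @export
cut_segments <- function(signal, train, window_ms) {
  fs <- signal$fs
  len <- round(window_ms * fs / 1000)
  pre_n <- round(len / 4)
  idx <- round((train$times - signal$t0) * fs) + 1L
  ok <- idx - pre_n >= 1L & idx + (len - pre_n) - 1L <= length(signal$samples)
  idx <- idx[ok]
  if (!length(idx)) stop("no segment fits the signal")
  offs <- (-pre_n):(len - pre_n - 1L)
  m <- matrix(signal$samples[rep(idx, each = len) + rep(offs, length(idx))],
              nrow = length(idx), byrow = TRUE)
  segment_set(m, fs, pre_n + 1L, window_ms,
              source_times = (idx - 1L) / fs + signal$t0)
}
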