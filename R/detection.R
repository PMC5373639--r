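# Threshold-crossing spike detection and its ROC evaluation against known
# spike times. Alpha (false positive) is normalized by the number of
# spike-free time bins so that it is a probability commensurate with beta
# (false negative).

#' Threshold-crossing spike detection
#'
#' Emits an event at each sample where the signal first crosses the
#' threshold in the stated polarity (negative-going by default, matching
#' extracellular troughs), then suppresses further events for
#' `dead_time_ms`.
#'
#' @param signal a [continuous_signal()].
#' @param threshold detection level (same units as the signal; negative
#'   for negative polarity).
#' @param polarity `"neg"` (downward crossings) or `"pos"`.
#' @param dead_time_ms suppression window after each event (ms).
#' @return A [spike_train()] of crossing times.
#' @export
detect_threshold <- function(signal, threshold, polarity = c("neg", "pos"),
                             dead_time_ms = 1) {
  stopifnot(inherits(signal, "continuous_signal"))
  polarity <- match.arg(polarity)
  if (dead_time_ms < 0) stop("dead_time_ms must be >= 0")
  x <- signal$samples
  n <- length(x)
  cross <- if (polarity == "neg") {
    which(x[-1L] < threshold & x[-n] >= threshold) + 1L
  } else {
    which(x[-1L] > threshold & x[-n] <= threshold) + 1L
  }
  if (n >= 1L) {
    first <- if (polarity == "neg") x[1L] < threshold else x[1L] > threshold
    if (first) cross <- c(1L, cross)
  }
  dead_n <- round(dead_time_ms * signal$fs / 1000)
  keep <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last > dead_n) {
      keep <- c(keep, i)
      last <- i
    }
  }
  spike_train((keep - 1L) / signal$fs + signal$t0, n / signal$fs)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching (closest pairs first) within `tol_ms`.
#' `beta` is the fraction of unmatched true spikes; `alpha` is the number
#' of unmatched detections divided by the number of `bin_ms` bins that
#' contain no true spike (the false-positive opportunities).
#'
#' @param detected,truth [spike_train()] objects.
#' @param tol_ms matching tolerance (ms).
#' @param duration recording length (s); defaults to `truth$duration`.
#' @param bin_ms bin width defining false-positive opportunities (ms).
#' @return A [detection_score()] (with `threshold = NA`).
#' @export
score_detection <- function(detected, truth, tol_ms = 0.5,
                            duration = truth$duration, bin_ms = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (tol_ms <= 0 || bin_ms <= 0) stop("tol_ms and bin_ms must be positive")
  dt <- detected$times
  tt <- truth$times
  tol <- tol_ms / 1000
  matched_d <- logical(length(dt))
  matched_t <- logical(length(tt))
  if (length(dt) && length(tt)) {
    # candidate pairs: each detection against its two bracketing truths
    j <- findInterval(dt, tt)
    cand <- rbind(cbind(seq_along(dt), j), cbind(seq_along(dt), j + 1L))
    cand <- cand[cand[, 2L] >= 1L & cand[, 2L] <= length(tt), , drop = FALSE]
    d <- abs(dt[cand[, 1L]] - tt[cand[, 2L]])
    ok <- d <= tol
    cand <- cand[ok, , drop = FALSE]
    d <- d[ok]
    for (r in order(d)) {
      i <- cand[r, 1L]; k <- cand[r, 2L]
      if (!matched_d[i] && !matched_t[k]) {
        matched_d[i] <- TRUE
        matched_t[k] <- TRUE
      }
    }
  }
  beta <- if (length(tt)) sum(!matched_t) / length(tt) else 0
  n_bins <- max(1L, floor(duration * 1000 / bin_ms))
  occupied <- length(unique(pmin(floor(tt * 1000 / bin_ms), n_bins - 1L)))
  n_opp <- max(1L, n_bins - occupied)
  alpha <- min(1, sum(!matched_d) / n_opp)
  detection_score(alpha, beta, NA_real_)
}

#' ROC curve over a threshold sweep
#'
#' Runs [detect_threshold()] at each threshold, scores against the truth,
#' and returns the (P(alpha), P(1 - beta)) curve sorted by alpha with
#' (0,0) and (1,1) anchors appended.
#'
#' @param signal a [continuous_signal()].
#' @param truth ground-truth [spike_train()].
#' @param thresholds numeric vector of levels; if `NULL`, 40 negative
#'   levels spanning 0.5 robust-sigma to 1.2x the maximal excursion.
#' @param polarity,dead_time_ms,tol_ms,bin_ms passed to the detector and
#'   scorer.
#' @return A [roc_curve()].
#' @export
roc <- function(signal, truth, thresholds = NULL,
                polarity = c("neg", "pos"), dead_time_ms = 1,
                tol_ms = 0.5, bin_ms = 1) {
  polarity <- match.arg(polarity)
  if (is.null(thresholds)) {
    sig0 <- estimate_noise_std(signal, truth)
    ext <- if (polarity == "neg") -min(signal$samples) else
      max(signal$samples)
    lv <- seq(0.5 * sig0, 1.2 * ext, length.out = 40L)
    thresholds <- if (polarity == "neg") -lv else lv
  }
  if (length(thresholds) < 2L)
    stop("need at least 2 thresholds spanning the excursion range")
  al <- be <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    det <- detect_threshold(signal, thresholds[i], polarity, dead_time_ms)
    sc <- score_detection(det, truth, tol_ms, truth$duration, bin_ms)
    al[i] <- sc$alpha
    be[i] <- sc$beta
  }
  roc_curve(c(al, 0, 1), c(1 - be, 0, 1),
            c(thresholds, NA_real_, NA_real_))
}

#' Detection error of an ROC curve
#'
#' `1 - AUC`, with the area under the curve computed by trapezoidal
#' integration over the alpha-sorted points. 0 for a perfect detector,
#' 0.5 for chance.
#'
#' @param curve a [roc_curve()].
#' @return Scalar in \[0, 1\].
#' @export
detection_error <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  a <- curve$alpha
  t <- curve$tpr
  if (length(a) < 2L) stop("ROC curve needs at least 2 points")
  auc <- sum(diff(a) * (t[-1L] + t[-length(t)]) / 2)
  1 - auc
}
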