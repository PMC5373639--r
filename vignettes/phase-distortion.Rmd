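---
title: "Filter phase distortion of extracellular spikes: model, metrics, correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter phase distortion of extracellular spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikephase)
```

## The problem

Extracellular recordings are routinely high-pass (or band-pass) filtered
before spike detection, to strip the local field potential and isolate
spiking activity. A filter is characterized by its magnitude response
$|H(f)|$ *and* its phase response $\varphi(f)$. Practitioners choose
filters by magnitude; the phase is usually ignored. Yet a causal recursive
filter such as the ubiquitous Butterworth band-pass has a *nonlinear*
phase: each frequency is delayed by a different amount, the group delay

$$\tau_g(f) \;=\; -\frac{d\varphi}{d\omega},$$

which for a 4-pole 300–6000 Hz Butterworth at 44 kHz swings from ~17
samples at 500 Hz to ~2.5 samples at 2 kHz. An action potential waveform
is a sum of sinusoids (for an 88-sample, 2 ms window, its power sits in
the 0.5–4 kHz DFT bins); delaying those constituents by different amounts
tears the waveform apart: the trough develops a delayed, smeared shape
with an additional late positive phase. This distorts every downstream
quantity — mean waveforms, width-based cell-type features, the SNR that
threshold detection depends on.

Three phase classes matter:

* **NLP** (nonlinear phase): the causal recursive filter itself.
* **LP** (linear phase): a symmetric FIR; all frequencies delayed by the
  same `order/2` samples — shape-preserving, merely shifted.
* **ZP** (zero phase): the same recursive filter run forward and then
  backward over the time-reversed signal. Phases cancel; the net
  magnitude is $|H(f)|^2$.

When only the causally filtered stream was stored, the distortion is
removable in retrospect: time-reverse, refilter with the *same* filter,
reverse back ("reversed refiltering"). The composition has zero net phase
and magnitude $|H|^2$ — identical to ZP filtering of the raw signal,
which is this package's master invariant (checked to $10^{-9}$ relative
RMS). When only threshold-crossing *segments* were stored, the same
trick works per segment after expanding the segment boundaries to
approximate the missing samples.

## The simulator (what the synthetic world is)

`assemble_signal()` builds a ground-truth world:

* **Spike times**: homogeneous Poisson process with an absolute
  refractory period. Inter-spike intervals are
  $t_{\mathrm{ref}} + \mathrm{Exp}(\lambda)$ with
  $t_{\mathrm{ref}} = 1$ ms by default, so the expected count over
  duration $T$ is $\lambda T / (1 + \lambda t_{\mathrm{ref}})$ and the
  ISI tail is exactly exponential (verified by a KS test at
  $\alpha = 0.01$). Default rate 10 Hz — an unremarkable tonic rate for
  the basal-ganglia populations this problem arises in; the rate only
  sets how many waveforms are averaged.
* **Template**: the analytic time derivative of a smooth double-Gaussian
  action-potential surrogate
  $g(u) = e^{-u^2/2} - 0.3\,e^{-(u-2)^2/8}$, giving a biphasic shape
  with a dominant negative trough (as extracellular spikes have), time-
  rescaled so the trough's full width at half height equals the requested
  `width_hh_ms` within one sample, peak-normalized to 1, decaying below
  1% of peak at both ends. Spikes are placed at integer sample positions
  (no sub-sample jitter); the template's trough lands exactly on the
  spike sample, which is the alignment contract every metric relies on.
* **Noise**: pink ($1/f$) background, synthesized spectrally — white
  Gaussian spectrum shaped by $f^{-1/2}$, DC zeroed, inverse transform,
  standardized — so the log–log PSD slope is $-1$ by construction and
  every realization is seed-reproducible. The noise is scaled to
  $\sigma = \mathrm{peak}/\mathrm{SNR}$ with the field's SNR definition:
  maximum absolute waveform amplitude over noise standard deviation.
  The default target SNR is 2.7.

**What a green test does and does not establish.** The generator
reproduces the *statistical skeleton* of an extracellular channel: renewal
spike times, a stereotyped biphasic waveform, $1/f$ background. It omits
bursting, multi-unit overlap, electrode drift, amplitude variability and
hardware spectral coloring. Green tests therefore establish properties of
the filtering/correction machinery, not claims about any biological
recording. One property of real spikes matters a great deal and is *not*
captured: see "Known limitations".

## Metrics

* **Mean waveform**: per-sample mean ± SD over windows cut around shared
  spike timestamps. Detection/sorting is done once on the undistorted
  signal, and the *same* timestamps are applied to raw, NLP- and
  ZP-filtered versions, so waveform differences are purely filter
  effects. The default window is 0.5 ms before to 1.5 ms after the
  trough (88 samples at the default 44 kHz) — the trough sits at 25% so
  the NLP's rightward-smeared shape stays in-window.
* **Distortion**: $D = \lVert w_{\mathrm{test}} - w_{\mathrm{ref}}
  \rVert_2 / \lVert w_{\mathrm{ref}} \rVert_2$, no re-alignment.
* **SNR**: $\max |w| / \sigma_{\mathrm{noise}}$, with $\sigma$ known in
  simulation or estimated as $1.4826 \times$ MAD of spike-free samples.
* **DFT reconstruction**: a mean waveform is resynthesized from its first
  $k$ DFT sinusoids (default 8, i.e. 0.5–4 kHz for the 2 ms window), DC
  excluded since the signals are high-passed. With all bins the
  reconstruction is exact (Parseval-checked to $10^{-9}$).

## Detection and its ROC

`detect_threshold()` emits an event at each first crossing (negative
polarity by default) and then holds off for a 1 ms dead time.
`score_detection()` matches detections to truth greedily, closest pair
first, within ±0.5 ms; $\beta$ is the unmatched-truth fraction. The
false-positive probability needs a denominator the literature never
states; we use the number of 1 ms bins containing no true spike, which
makes $\alpha$ a probability commensurate with $\beta$. The ROC is the
set of $(\alpha, 1-\beta)$ points over 40 thresholds spanning
$0.5\sigma$ to $1.2\times$ the maximal excursion, with $(0,0)$ and
$(1,1)$ anchors, and the detection error is $1 - \mathrm{AUC}$
(trapezoidal).

A construction caveat, visible in the test results: at shallow
thresholds the dead time turns detections into a renewal process with
~1 ms spacing, so 10–20% of true spikes have no detection within
±0.5 ms and the curve's right end droops below $1-\beta = 1$. That puts
an SNR-independent floor of roughly 0.1 under the trapezoidal error.
The well-separated regime (deep thresholds) is unaffected, and the
NLP-worse-than-ZP ordering is robust, but the *absolute* error values
saturate at this floor once the SNR is high enough — which is why the
zero-phase error is not monotone in SNR while the NLP error is.

## Correction

**Continuous**: `correct_continuous()` is literally
`rev(filter(rev(x)))` with the same causal filter, in cascaded
second-order sections. Its output equals `apply_zero_phase()` of the raw
signal away from the edges; interior agreement is at machine precision
once both transients (length $\log(10^{-12})/\log r_{\max} \approx 900$
samples for the default design) have decayed.

**Segmented**: each snippet is expanded on both sides, corrected, and
cropped back. Expansion modes: `zeros`, `constant` (repeat edge),
`linear` (continue the line through the two outermost samples), `mirror`
(reflect without repeating the edge sample). Zero padding inserts a step
at the boundary of any non-decayed waveform; the backward filter pass
smears that step into the segment, which is the boundary artifact the
other modes reduce.

**Default pad length: 0.5 ms per side.** The benefit of padding
saturates once the pad covers the filter's edge transient (group delay
~20 samples and pole 1/e decay ~33 samples at the 300 Hz edge, i.e.
~0.5–0.75 ms), while the cost of the `linear` mode grows linearly with
pad length — its extrapolated ramp ends in a discontinuity of size
(slope × pad), which re-enters the segment through the backward pass. At
a pad equal to the segment width (2 ms), linear expansion actually
scores *below* zero padding; at 0.5 ms it is clearly better (0.985 vs
0.933 mean accuracy in the default sweep). Hence a fixed, transient-
scaled default rather than one proportional to the segment.

**Accuracy conventions.** Accuracy is $\max(0, 1 - D)$ evaluated on a
fixed 2 ms region of interest around the alignment point, not on the
full segment — otherwise wider segments are penalized merely for
revealing more of the zero-phase ringing, and the metric is not
comparable across segment widths. Two references are reported by
`run_sweep()`: the ZP-filtered waveform (`accuracy_*`), which isolates
the boundary effect because corrected and reference then share the
$|H|^2$ magnitude; and the raw waveform (`accuracy_raw_*`), the
comparison the original-waveform figures make. The cutoff-frequency
trend (accuracy falling as the high-pass edge rises) only exists in the
raw-referenced metric: it is driven by the magnitude loss near the
waveform's band, which the ZP reference cancels by construction.
Segment-sweep averages use only spikes whose neighbours lie outside the
segment window; colliding spikes are a different failure mode than
boundary truncation.

## Numerical choices

* Recursive designs are cascaded biquads paired as conjugate pole pairs
  each with one zero at $z = 1$ and one at $z = -1$; direct-form
  coefficients of a 300 Hz edge at 44 kHz are numerically fragile.
  Band edges are pre-warped so $|H|$ is exactly $1/\sqrt 2$ at both.
* "4-pole band-pass" means four poles total (2nd-order low-pass
  prototype), matching the common MATLAB/SciPy convention.
* FIR taps are windowed-sinc with an explicitly symmetrized Hamming
  window (exact tap symmetry to the last ulp), unit gain at the
  arithmetic band centre; "similar bandwidth" is read as the same
  300–6000 Hz edges.
* Phase is unwrapped on a dense grid (≥ 8192 points to Nyquist) before
  interpolation at requested frequencies; group delay is a central
  difference of that phase (±0.25 Hz). A steady-state sinusoid is
  shifted by the *phase* delay $-\varphi/\omega$; group delay is
  measured on narrowband tone bursts (energy-centroid shift).
* Zero-phase edge handling: odd-symmetric reflection padding, default
  $3(4 n_{\mathrm{sections}} + 1)$ samples per side, zero initial
  conditions.
* Signals are stored as little-endian float32 with a JSON sidecar; all
  times are float64 seconds; windows are half-open in samples. The
  default 44 kHz rate is implied by the 88-sample / 2 ms waveform
  convention.

## Known limitations

The double-Gaussian-derivative surrogate has genuine spectral mass below
300 Hz once its trough is ≳ 0.4 ms wide at half height — unavoidably: a
lobe of width $w$ concentrates power near $0.3\text{–}0.5/w$ kHz, so a
1 ms trough peaks around 300–500 Hz, inside the high-pass transition
band. Consequences, all visible as deliberate failures in
`test-acceptance.R`:

* Even zero-phase filtering changes wide templates measurably
  ($D(\mathrm{raw}, \mathrm{ZP})$ grows to ~0.6 at 1 ms), so a
  "ZP distance < 0.05 at every width/cutoff" idealization cannot hold
  for any waveform with a genuinely wide trough.
* For this surrogate the causal NLP filter mostly *delays* the trough
  rather than attenuating it, while ZP attenuates out-of-band mass twice
  ($|H|^2$); the filtered-SNR ratio NLP/ZP therefore lands slightly
  *above* 1, whereas recordings whose waveforms sit strictly inside the
  passband show ratios well below 1 (reported real-data range
  0.49–0.84). Reproducing that regime would require a wide-trough
  template with no sub-300 Hz energy, which does not exist.
* For the same reason, correcting a segment does not raise its peak
  amplitude here: there was no NLP peak loss to recover, and the
  correction's $|H|^2$ magnitude slightly lowers it.

None of this affects the correction machinery itself (the reversed-
refiltering identity holds at $10^{-9}$), only which *magnitude*-side
idealizations the synthetic world can exhibit. The distortion-ordering,
width-trend, cutoff-trend, detection-ordering and segment-correction
properties all hold in this world and are enforced by the test suite.
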