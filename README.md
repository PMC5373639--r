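# spikephase

Phase distortion of extracellular spike waveforms: simulation,
measurement and correction.

## Why

High-pass filtering is a mandatory pre-processing step for extracellular
spike data, and nearly every acquisition system and offline toolchain
does it with a causal recursive filter (typically a 4-pole Butterworth
band-pass, 300–6000 Hz). Such filters have a **nonlinear phase**
response: the group delay τ<sub>g</sub>(f) = −dφ/dω differs across the
frequencies that make up an action potential, so the filtered spike is
not just delayed, it is *reshaped* — a shallower trough followed by a
spurious late positive phase. That lowers the waveform SNR
(max |w| / σ<sub>noise</sub>), degrades threshold-crossing detection,
and corrupts any analysis that reads the waveform.

`spikephase` provides, for single-channel data:

* a ground-truth simulator: Poisson spike trains with a 1 ms absolute
  refractory period, convolved with a biphasic spike template of
  controllable half-height width, in pink (1/f) noise at a target SNR;
* filter design and application for the three phase classes — causal
  Butterworth (NLP), symmetric Hamming FIR (LP), forward–backward
  zero-phase (ZP) — plus magnitude/phase/group-delay evaluation
  (no external DSP library: the cascaded-biquad designs are validated
  against SciPy to machine precision);
* distortion metrics: spike-triggered mean waveforms over shared
  timestamps, normalized Euclidean distance
  D = ‖w − w<sub>ref</sub>‖/‖w<sub>ref</sub>‖, SNR, and low-order DFT
  waveform reconstruction;
* ROC-based detection scoring (α = false positives per spike-free 1 ms
  bin, β = missed-spike fraction, detection error = 1 − AUC);
* distortion **correction** by reversed refiltering — for continuous
  signals (exactly equivalent to zero-phase filtering of the raw data)
  and for stored threshold-crossing segments, with zeros / constant /
  linear / mirror boundary expansions.

## Worked example

```r
library(spikephase)

nlp <- design_filter(filter_spec("NLP", "butterworth", 4, c(300, 6000),
                                 fs = 44000))
sim <- assemble_signal(sim_config(rate = 10, duration = 4,
                                  width_hh_ms = 0.4, target_snr = 2.7,
                                  seed = 1))
sim$train
#> <spike_train> 40 spikes over 4 s (rate 10.00 Hz)

distorted <- apply_causal(sim$signal, nlp)       # what the rig stores
zp        <- apply_zero_phase(sim$signal, nlp)   # offline gold standard
corrected <- correct_continuous(distorted, nlp)  # reversed refiltering

w_raw <- mean_waveform(sim$signal, sim$train)
round(c(
  D_nlp        = normalized_distance(w_raw, mean_waveform(distorted, sim$train)),
  D_zp         = normalized_distance(w_raw, mean_waveform(zp, sim$train)),
  D_corrected  = normalized_distance(w_raw, mean_waveform(corrected, sim$train)),
  D_corr_vs_zp = normalized_distance(mean_waveform(zp, sim$train),
                                     mean_waveform(corrected, sim$train))
), 4)
#>        D_nlp         D_zp  D_corrected D_corr_vs_zp
#>       0.6266       0.1068       0.1068       0.0000

c(err_nlp = detection_error(roc(distorted, sim$train)),
  err_zp  = detection_error(roc(zp, sim$train)))
#>   err_nlp    err_zp
#> 0.1678125 0.1454104
```

Reading: the causally filtered waveform sits at distance 0.63 from the
raw one; zero-phase filtering leaves only the unavoidable magnitude
effect (0.11); reversed refiltering of the distorted stream reproduces
the zero-phase result to machine precision (`D_corr_vs_zp = 0`), and the
detection error of the corrected/ZP signal is below the distorted one.

Segmented data:

```r
tr  <- isolated_spikes(sim$train, 0.012)
seg <- cut_segments(distorted, tr, window_ms = 8)
fix <- correct_segments(seg, nlp, mode = "linear")   # pad 0.5 ms/side
```

Parameter sweeps (`run_sweep`) and the figure-style end-to-end recipes
(`run_experiment("phase_demo" | "width_sweep" | "cutoff_sweep" |
"roc_sweep" | "continuous_correction" | "segment_correction", out_dir)`)
write CSV/JSON artifacts with the resolved configuration embedded. A CLI
wraps all of it:

```sh
Rscript -e 'spikephase::spikephase_cli()' simulate --rate 10 --duration 4 \
    --snr 2.7 --seed 1 --out sim
Rscript -e 'spikephase::spikephase_cli()' correct --mode continuous \
    --signal filtered.f32 --filter-spec filt.json --out corrected.f32
```

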