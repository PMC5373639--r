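# Reversed refiltering and segment boundary expansion.

test_that("correct_continuous composed with the causal filter equals
           zero-phase filtering (master equivalence)", {
  for (spec in list(c(4, 300, 6000), c(2, 300, 6000), c(4, 500, 8000),
                    c(6, 100, 3000))) {
    fr <- design_filter(filter_spec("NLP", "butterworth", spec[1],
                                    spec[2:3], FS))
    x <- continuous_signal(generate_pink_noise(FS, FS,
                                               seed = 600 + spec[1]), FS)
    a <- correct_continuous(apply_causal(x, fr), fr)$samples
    b <- apply_zero_phase(x, fr)$samples
    # interior: past the slowest pole's decay to 1e-12
    margin <- ceiling(log(1e-12) / log(max(Mod(fr$poles)))) + 50L
    int <- margin:(FS - margin)
    expect_lt(rel_rms(a[int], b[int]), 1e-9)
  }
  expect_error(correct_continuous(continuous_signal(1:10, FS),
                                  default_fir()), "recursive")
})

test_that("a causally filtered passband sinusoid is re-aligned by the
           correction", {
  tt <- (0:(FS / 4)) / FS
  s <- sin(2 * pi * 1000 * tt)
  sig <- continuous_signal(s, FS)
  cor <- correct_continuous(apply_causal(sig, default_nlp()),
                            default_nlp())$samples
  int <- 3000:8000
  lags <- -5:5
  cc <- vapply(lags, function(L) sum(s[int - L] * cor[int]), numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("correction restores the continuous mean waveform", {
  sim <- sim_clean(0.4, seed = 3)
  nlp <- default_nlp()
  distorted <- apply_causal(sim$signal, nlp)
  corrected <- correct_continuous(distorted, nlp)
  zp <- apply_zero_phase(sim$signal, nlp)
  w_raw <- mean_waveform(sim$signal, sim$train)
  d_nlp <- normalized_distance(w_raw, mean_waveform(distorted, sim$train))
  d_cor <- normalized_distance(w_raw, mean_waveform(corrected, sim$train))
  expect_lt(d_cor, d_nlp)
  # and matches the zero-phase waveform almost exactly
  expect_lt(normalized_distance(mean_waveform(zp, sim$train),
                                mean_waveform(corrected, sim$train)),
            1e-6)
})

test_that("segment expansions implement their closed forms", {
  expect_identical(expand_segment(c(0, 1, 2), "linear", 3),
                   c(-3, -2, -1, 0, 1, 2, 3, 4, 5))
  expect_identical(expand_segment(c(5, 1), "zeros", 2),
                   c(0, 0, 5, 1, 0, 0))
  expect_identical(expand_segment(c(5, 1), "constant", 2),
                   c(5, 5, 5, 1, 1, 1))
  expect_identical(expand_segment(c(1, 2, 3), "mirror", 2),
                   c(3, 2, 1, 2, 3, 2, 1))
  expect_identical(expand_segment(1:4, "zeros", 0), 1:4)
  expect_error(expand_segment(1:4, "zeros", -1), "non-negative")
  expect_error(expand_segment(c(1, 2), "linear", 1), "too short")
})

test_that("segment correction approaches the continuous correction for
           wide, decayed segments", {
  sim <- sim_clean(0.4, seed = 3)
  nlp <- default_nlp()
  distorted <- apply_causal(sim$signal, nlp)
  corrected_cont <- correct_continuous(distorted, nlp)
  tr <- isolated_spikes(sim$train, 0.03)
  seg <- cut_segments(distorted, tr, 16)
  ref <- cut_segments(corrected_cont, tr, 16)
  for (m in c("zeros", "linear")) {
    segc <- correct_segments(seg, nlp, m)
    for (i in seq_len(min(4, nrow(seg$segments)))) {
      expect_lt(rel_rms(segc$segments[i, ], ref$segments[i, ]), 1e-3)
    }
  }
})

test_that("corrected segments beat distorted segments against the
           zero-phase reference", {
  sim <- sim_clean(0.4, seed = 3)
  nlp <- default_nlp()
  distorted <- apply_causal(sim$signal, nlp)
  zp <- apply_zero_phase(sim$signal, nlp)
  tr <- isolated_spikes(sim$train, 0.012)
  seg <- cut_segments(distorted, tr, 8)
  ref <- cut_segments(zp, tr, 8)
  segc <- correct_segments(seg, nlp, "linear")
  for (i in seq_len(nrow(seg$segments))) {
    expect_lt(normalized_distance(ref$segments[i, ], segc$segments[i, ]),
              normalized_distance(ref$segments[i, ], seg$segments[i, ]))
  }
})

test_that("correction accuracy has its closed forms", {
  w <- c(1, 2, -3, 4)
  expect_equal(correction_accuracy(w, w), 1)
  # orthogonal equal-norm vectors: D = sqrt(2), clipped to 0
  expect_equal(correction_accuracy(c(1, 0), c(0, 1)), 0)
  expect_error(correction_accuracy(w, numeric(4)), "zero norm")
})

test_that("run_sweep has the stated cardinality and is seed-deterministic", {
  cfg <- sim_config(rate = 10, duration = 2, target_snr = Inf)
  tab <- run_sweep("width", seq(0.2, 1, 0.2), seeds = c(1, 2, 3),
                   config = cfg)
  expect_identical(nrow(tab), 5L * 3L * 2L)
  tab2 <- run_sweep("width", seq(0.2, 1, 0.2), seeds = c(1, 2, 3),
                    config = cfg)
  expect_identical(tab, tab2)
  expect_error(run_sweep("width", numeric(0)), "empty")
})
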