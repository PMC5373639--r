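# Mean waveforms, distance, SNR, DFT reconstruction.

test_that("mean waveform of a noise-free signal equals the template
           window", {
  sim <- sim_clean(0.4, seed = 3)
  tpl <- sim$template
  iso <- isolated_spikes(sim$train, 0.005)
  w <- mean_waveform(sim$signal, iso)
  expect_identical(length(w$mean), 88L)
  ref <- tpl$samples[(tpl$align_index - 22):(tpl$align_index + 65)]
  expect_equal(w$mean, ref, tolerance = 1e-9)
  expect_lt(max(w$std), 1e-9)

  # single spike: mean equals that snippet exactly
  one <- spike_train(iso$times[1], sim$train$duration)
  w1 <- mean_waveform(sim$signal, one)
  expect_identical(w1$n_spikes, 1L)
  expect_equal(w1$mean, ref, tolerance = 1e-12)
})

test_that("mean waveform drops out-of-bounds spikes and errors when empty", {
  sig <- continuous_signal(stats::rnorm(441), FS)
  expect_warning(w <- mean_waveform(sig, spike_train(c(0.0001, 0.005), 0.01)),
                 "dropped")
  expect_identical(w$n_spikes, 1L)
  expect_error(mean_waveform(sig, spike_train(numeric(0), 0.01)), "empty")
  expect_error(suppressWarnings(
    mean_waveform(sig, spike_train(0.0001, 0.01))), "all spikes")
})

test_that("the error of the mean shrinks like 1/sqrt(n)", {
  set.seed(77)
  tpl <- make_template(0.4, FS)$samples
  L <- length(tpl)
  errs <- vapply(c(10, 100, 1000), function(n) {
    gap <- L + 10L
    x <- stats::rnorm(n * gap + 2L * gap)
    idx <- gap + (0:(n - 1L)) * gap  # 1-based alignment sample
    for (i in idx) x[i:(i + L - 1L)] <- x[i:(i + L - 1L)] + tpl
    sig <- continuous_signal(x, FS)
    tr <- spike_train((idx - 1L + which.min(tpl) - 1L) / FS,
                      length(x) / FS)
    w <- mean_waveform(sig, tr)
    ref <- tpl[(which.min(tpl) - 22):(which.min(tpl) + 65)]
    sqrt(mean((w$mean - ref)^2))
  }, numeric(1))
  # consecutive ratios ~ sqrt(10) = 3.16
  expect_gt(errs[1] / errs[2], 1.8)
  expect_lt(errs[1] / errs[2], 5.5)
  expect_gt(errs[2] / errs[3], 1.8)
  expect_lt(errs[2] / errs[3], 5.5)
})

test_that("normalized distance satisfies its closed forms and metric
           properties", {
  set.seed(5)
  w <- stats::rnorm(88)
  expect_equal(normalized_distance(w, w), 0)
  expect_equal(normalized_distance(w, 2 * w), 1)
  expect_equal(normalized_distance(w, -w), 2)
  expect_error(normalized_distance(numeric(88), w), "zero norm")
  expect_error(normalized_distance(w, stats::rnorm(40)), "equal length")
  # symmetry up to the normalizing constant, triangle inequality
  for (i in 1:20) {
    a <- stats::rnorm(30); b <- stats::rnorm(30); c <- stats::rnorm(30)
    na <- sqrt(sum(a^2))
    d_ab <- normalized_distance(a, b) * na
    d_ba <- normalized_distance(b, a) * sqrt(sum(b^2))
    expect_equal(d_ab, d_ba, tolerance = 1e-12)
    expect_lte(d_ab,
               normalized_distance(a, c) * na +
                 normalized_distance(c, b) * sqrt(sum(c^2)) + 1e-12)
  }
})

test_that("SNR is peak over noise SD", {
  expect_equal(snr_of(c(1, -5, 2), 2), 2.5)
  expect_equal(snr_of(numeric(10), 1), 0)
  expect_error(snr_of(1:3, 0), "positive")
  sim <- assemble_signal(sim_config(rate = 10, duration = 2,
                                    target_snr = 2.7, seed = 8))
  expect_equal(snr_of(sim$template$samples, sim$noise_sd), 2.7)
})

test_that("noise SD estimation is MAD-consistent and excludes spikes", {
  set.seed(31)
  sig <- continuous_signal(stats::rnorm(2e5), FS)
  tr <- spike_train(c(1, 2, 3) / 2, length(sig$samples) / FS)
  expect_equal(estimate_noise_std(sig, tr), 1, tolerance = 0.02)

  sim <- sim_clean(0.4, seed = 3)
  expect_lt(estimate_noise_std(sim$signal, sim$train, guard_ms = 4), 0.02)
  short <- continuous_signal(stats::rnorm(441), FS)
  expect_error(estimate_noise_std(short, spike_train(0.005, 0.01),
                                  guard_ms = 20), "spike-free")
})

test_that("DFT reconstruction is complete, exact on single bins, and
           Parseval-consistent", {
  set.seed(6)
  x <- stats::rnorm(88)
  # all bins plus DC restore the signal
  rec <- dft_reconstruct(x, 44L) + mean(x)
  expect_equal(rec, x, tolerance = 1e-9)
  # single cycle of the fundamental (500 Hz over a 2 ms window)
  n <- 0:87
  s <- cos(2 * pi * n / 88 + 0.7)
  expect_equal(dft_reconstruct(s, 1L), s, tolerance = 1e-9)
  expect_error(dft_reconstruct(x, 0L), "n_components")
  expect_error(dft_reconstruct(x, 45L), "n_components")

  # captured energy equals the direct DFT-bin energy sum
  tpl <- make_template(0.4, FS)$samples[1:88]
  rec8 <- dft_reconstruct(tpl, 8L)
  X <- stats::fft(tpl)
  bin_energy <- sum(2 * Mod(X[2:9])^2 / 88)
  expect_equal(sum(rec8^2), bin_energy, tolerance = 1e-9)
})

test_that("ZP-filtered waveforms stay closer to raw than NLP for every
           width, and NLP adds a late positive deflection", {
  nlp <- default_nlp()
  for (w in c(0.2, 0.4, 0.8)) {
    sim <- sim_clean(w, seed = 3)
    wr <- mean_waveform(sim$signal, sim$train)
    wn <- mean_waveform(apply_causal(sim$signal, nlp), sim$train)
    wz <- mean_waveform(apply_zero_phase(sim$signal, nlp), sim$train)
    expect_lt(normalized_distance(wr, wz), normalized_distance(wr, wn))
    trail_raw <- max(wr$mean[which.min(wr$mean):88])
    trail_nlp <- max(wn$mean[which.min(wn$mean):88])
    expect_gt(trail_nlp, 1.5 * trail_raw)
  }
})
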