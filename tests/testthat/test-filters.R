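# Filter design and application. Reference values marked "external oracle"
# were computed with an independent DSP implementation (SciPy 1.17) on the
# identical design problem.

test_that("Butterworth band-pass hits -3 dB at its edges and is stable", {
  fr <- default_nlp()
  expect_equal(Mod(freq_response(fr, 300)), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(Mod(freq_response(fr, 6000)), 1 / sqrt(2), tolerance = 1e-6)
  expect_true(all(Mod(fr$poles) < 1))
  # external oracle: |H(1500)| = 0.99999897
  expect_gt(Mod(freq_response(fr, 1500)), 0.99)
  expect_equal(Mod(freq_response(fr, 1500)), 0.99999897, tolerance = 1e-6)
  # external oracle: unwrapped phase and group delay at 1 kHz
  expect_equal(phase_response(fr, 1000), 0.21364411, tolerance = 1e-6)
  expect_equal(group_delay(fr, 1000), 4.86041692, tolerance = 1e-3)
})

test_that("designs reject invalid bands and odd band-pass orders", {
  expect_error(filter_spec("NLP", "butterworth", 4, c(300, 30000), FS),
               "Nyquist")
  expect_error(filter_spec("NLP", "butterworth", 3, c(300, 6000), FS),
               "even")
  expect_error(filter_spec("NLP", "butterworth", 4, c(6000, 300), FS),
               "low < high")
  expect_error(filter_spec("ZP", "fir_hamming", 20, c(300, 6000), FS),
               "recursive")
})

test_that("Hamming FIR taps are symmetric and match the external oracle", {
  fr <- default_fir()
  h <- fr$taps
  expect_length(h, 21L)
  expect_identical(h, rev(h))
  # external oracle: scipy.signal.firwin(21, [300, 6000], 'hamming')
  expect_equal(h[11], 0.2727371148, tolerance = 1e-8)
  expect_equal(h[1], 0.0009123012, tolerance = 1e-6)
  expect_equal(h[10], 0.2335044865, tolerance = 1e-8)
})

test_that("causal application is strictly causal and matches a direct-form
           recursion oracle", {
  fr <- default_nlp()
  x <- numeric(500)
  x[101] <- 1
  y <- apply_causal(continuous_signal(x, FS), fr)$samples
  expect_identical(y[1:100], numeric(100))
  expect_true(any(y[101:120] != 0))

  set.seed(11)
  x <- stats::rnorm(1500)
  y <- apply_causal(continuous_signal(x, FS), fr)$samples
  expect_lt(rel_rms(y, direct_form_sos(x, fr$sos)), 1e-9)
  # FIR path against direct convolution
  ff <- default_fir()
  yf <- apply_causal(continuous_signal(x, FS), ff)$samples
  conv <- stats::convolve(x, rev(ff$taps), type = "open")[1:1500]
  expect_lt(rel_rms(yf, conv), 1e-12)
})

test_that("narrowband tone bursts are delayed by the group delay, pure
           sinusoids by the phase delay", {
  fr <- default_nlp()
  tt <- (0:(FS / 4)) / FS
  for (f0 in c(500, 1000, 2000)) {
    # group delay acts on the envelope of a narrowband burst: measure the
    # energy-centroid shift
    x <- exp(-(tt - 0.1)^2 / (2 * 0.004^2)) * sin(2 * pi * f0 * tt)
    y <- apply_causal(continuous_signal(x, FS), fr)$samples
    cx <- sum(seq_along(x) * x^2) / sum(x^2)
    cy <- sum(seq_along(y) * y^2) / sum(y^2)
    expect_lt(abs((cy - cx) - group_delay(fr, f0)), 0.5)
  }
  # steady-state sinusoid: shifted by the phase delay -phi/omega
  s <- sin(2 * pi * 1000 * tt)
  ys <- apply_causal(continuous_signal(s, FS), fr)$samples
  int <- 3000:8000
  ph <- phase_response(fr, 1000)
  omega <- 2 * pi * 1000 / FS
  lagf <- seq(-4, 4, by = 0.25)
  cc <- vapply(lagf, function(L)
    sum(sin(2 * pi * 1000 * (tt[int] - L / FS)) * ys[int]), numeric(1))
  expect_lt(abs(lagf[which.max(cc)] - (-ph / omega)), 0.5)
})

test_that("zero-phase equals the reverse-filter-reverse composition and
           has zero lag and squared magnitude", {
  fr <- default_nlp()
  set.seed(12)
  x <- stats::rnorm(6000)
  pad <- 3L * (4L * nrow(fr$sos) + 1L)
  # independent composition oracle with identical odd-reflection padding
  xp <- c(2 * x[1] - x[(pad + 1):2], x,
          2 * x[6000] - x[5999:(6000 - pad)])
  y1 <- apply_causal(continuous_signal(xp, FS), fr)$samples
  y2 <- rev(apply_causal(continuous_signal(rev(y1), FS), fr)$samples)
  oracle <- y2[(pad + 1):(pad + 6000)]
  got <- apply_zero_phase(continuous_signal(x, FS), fr)$samples
  expect_lt(rel_rms(got, oracle), 1e-9)

  # interior sinusoid: lag 0, gain |H|^2 (causal gain |H|)
  tt <- (0:(FS / 2)) / FS
  s <- sin(2 * pi * 1000 * tt)
  sig <- continuous_signal(s, FS)
  int <- 4000:18000
  zp <- apply_zero_phase(sig, fr)$samples
  ca <- apply_causal(sig, fr)$samples
  lags <- -5:5
  cc <- vapply(lags, function(L) sum(s[int - L] * zp[int]), numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
  h1 <- Mod(freq_response(fr, 1000))
  expect_equal(sqrt(mean(zp[int]^2)) / sqrt(mean(s[int]^2)), h1^2,
               tolerance = 0.01)
  expect_equal(sqrt(mean(ca[int]^2)) / sqrt(mean(s[int]^2)), h1,
               tolerance = 0.01)

  # DC offset is removed by the band-pass stopband at 0 Hz
  dc <- apply_zero_phase(continuous_signal(rep(2, 4000), FS), fr)$samples
  expect_lt(max(abs(dc[1000:3000])), 1e-6)
})

test_that("phase responses: ZP identically zero, FIR exactly linear,
           Butterworth measurably nonlinear", {
  zp <- design_filter(filter_spec("ZP", "butterworth", 4, c(300, 6000), FS))
  fg <- seq(300, 6000, by = 25)
  expect_identical(phase_response(zp, fg), rep(0, length(fg)))
  expect_identical(group_delay(zp, fg), rep(0, length(fg)))

  ph <- phase_response(default_fir(), fg)
  fit <- stats::lm(ph ~ fg)
  expect_lt(max(abs(stats::resid(fit))), 1e-9)
  expect_equal(group_delay(default_fir(), c(500, 1000, 3000, 5000)),
               rep(10, 4), tolerance = 1e-6)

  phb <- phase_response(default_nlp(), fg)
  fitb <- stats::lm(phb ~ fg)
  expect_gt(max(abs(stats::resid(fitb))), 0.1)
  gd <- group_delay(default_nlp(), fg)
  expect_gt(stats::sd(gd), 0)
})

test_that("three-sinusoid summation: ZP superimposes, LP is a pure shift,
           NLP is not any pure shift of the input", {
  tt <- (0:8819) / FS
  x <- sin(2 * pi * 500 * tt) + sin(2 * pi * 1000 * tt) +
    sin(2 * pi * 2000 * tt)
  sig <- continuous_signal(x, FS)
  int <- 2000:7000
  nd <- function(a, b) sqrt(sum((b - a)^2)) / sqrt(sum(a^2))
  zp <- apply_zero_phase(sig, default_nlp())$samples
  expect_lt(nd(x[int], zp[int]), 0.1)
  lp <- apply_causal(sig, default_fir())$samples
  expect_lt(nd(x[int - 10], lp[int]), 0.1)
  nl <- apply_causal(sig, default_nlp())$samples
  best <- min(vapply(0:40, function(s) nd(x[int - s], nl[int]), numeric(1)))
  expect_gt(best, 0.05)
})

test_that("applying a filter checks the sampling rate", {
  sig <- continuous_signal(stats::rnorm(100), 30000)
  expect_error(apply_causal(sig, default_nlp()), "mismatch")
  expect_error(apply_zero_phase(sig, default_nlp()), "mismatch")
  expect_error(apply_zero_phase(continuous_signal(rnorm(100), FS),
                                default_fir()), "recursive")
})
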