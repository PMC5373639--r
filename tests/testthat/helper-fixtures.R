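# Shared fixtures, built in code and memoized per test run.

FS <- 44000

default_nlp <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- design_filter(filter_spec("NLP", "butterworth", 4,
                                          c(300, 6000), FS))
    cache
  }
})

default_fir <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- design_filter(filter_spec("LP", "fir_hamming", 20,
                                          c(300, 6000), FS))
    cache
  }
})

# noise-free simulation reused across metric tests
sim_clean <- local({
  cache <- list()
  function(width = 0.4, seed = 3, duration = 4) {
    key <- paste(width, seed, duration)
    if (is.null(cache[[key]]))
      cache[[key]] <<- assemble_signal(sim_config(
        rate = 10, duration = duration, width_hh_ms = width,
        target_snr = Inf, fs = FS, seed = seed))
    cache[[key]]
  }
})

# independent direct-form-I biquad cascade, sample-by-sample (oracle)
direct_form_sos <- function(x, sos) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    y <- numeric(length(x))
    for (n in seq_along(x)) {
      y[n] <- b[1] * x[n]
      if (n > 1) y[n] <- y[n] + b[2] * x[n - 1] - a[2] * y[n - 1]
      if (n > 2) y[n] <- y[n] + b[3] * x[n - 2] - a[3] * y[n - 2]
    }
    x <- y
  }
  x
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

spearman <- function(x, y) stats::cor(x, y, method = "spearman")
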