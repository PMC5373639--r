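# Desk-scale experiment recipes and the command-line entry point. Each
# recipe writes its artifacts (signals, events, waveform CSVs, metric
# JSON, sweep tables) plus a JSON-lines log embedding the resolved
# configuration, so a run is reproducible from its output directory alone.

recipe_names <- c("phase_demo", "width_sweep", "cutoff_sweep", "roc_sweep",
                  "continuous_correction", "segment_correction")

log_line <- function(con, event, data = list()) {
  writeLines(jsonlite::toJSON(c(list(ts = "run", event = event), data),
                              auto_unbox = TRUE, digits = NA), con)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

default_experiment_config <- function(seed) {
  list(fs = 44000, band = c(300, 6000), order = 4L, rate = 10,
       duration = 4, width_hh_ms = 0.4, target_snr = 2.7, seed = seed,
       widths = seq(0.1, 1, by = 0.1),
       cutoffs = c(100, 200, 300, 500, 750, 1000),
       snr_grid = c(1.5, 2, 2.7, 4), n_seeds = 10L,
       segment_widths_ms = c(2, 4, 8, 16))
}

#' Run an end-to-end experiment recipe
#'
#' Recipes reproduce the package's standard workflows at desk scale:
#' `phase_demo` (three pass-band sinusoids through the ZP/LP/NLP filters
#' plus their phase responses), `width_sweep` and `cutoff_sweep`
#' (distortion versus template width / high-pass cutoff),
#' `roc_sweep` (detection error versus SNR for NLP and ZP filtering),
#' `continuous_correction` (reversed refiltering of a continuous signal)
#' and `segment_correction` (segment-width x expansion-mode accuracy).
#'
#' @param recipe one of the names above.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing every random draw.
#' @param config named list of overrides to the recipe defaults.
#' @return Invisibly, a named list of the files written.
#' @export
run_experiment <- function(recipe, out_dir, seed = 1L, config = list()) {
  if (!recipe %in% recipe_names)
    stop("unknown recipe '", recipe, "'; valid recipes: ",
         paste(recipe_names, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(default_experiment_config(seed), config)
  cfg$seed <- as.integer(cfg$seed)
  logf <- file.path(out_dir, "run_log.jsonl")
  con <- file(logf, "w")
  on.exit(close(con))
  log_line(con, "start", list(recipe = recipe, config = cfg))
  files <- c(log = logf)
  p <- function(name) file.path(out_dir, name)

  if (recipe == "phase_demo") {
    fs <- cfg$fs
    tt <- (0:round(0.02 * fs)) / fs
    freqs <- c(500, 1000, 2000)
    x <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * tt)))
    sig <- continuous_signal(x, fs)
    specs <- list(ZP = filter_spec("ZP", "butterworth", cfg$order, cfg$band, fs),
                  LP = filter_spec("LP", "fir_hamming", 20L, cfg$band, fs),
                  NLP = filter_spec("NLP", "butterworth", cfg$order, cfg$band, fs))
    out <- data.frame(t = tt, input = x)
    resp <- data.frame(freq_hz = seq(50, fs / 2 - 50, by = 50))
    for (nm in names(specs)) {
      fr <- design_filter(specs[[nm]])
      out[[nm]] <- apply_filter(sig, fr)$samples
      resp[[paste0("mag_", nm)]] <- Mod(freq_response(fr, resp$freq_hz))
      resp[[paste0("phase_", nm)]] <- phase_response(fr, resp$freq_hz)
      resp[[paste0("gd_", nm)]] <- group_delay(fr, resp$freq_hz)
    }
    utils::write.csv(out, p("filtered_sinusoids.csv"), row.names = FALSE)
    utils::write.csv(resp, p("responses.csv"), row.names = FALSE)
    files <- c(files, signals = p("filtered_sinusoids.csv"),
               responses = p("responses.csv"))
  } else if (recipe %in% c("width_sweep", "cutoff_sweep")) {
    vary <- if (recipe == "width_sweep") "width" else "cutoff"
    grid <- if (vary == "width") cfg$widths else cfg$cutoffs
    tab <- run_sweep(vary, grid, seeds = cfg$seed,
                     config = sim_config(rate = cfg$rate,
                                         duration = cfg$duration,
                                         width_hh_ms = cfg$width_hh_ms,
                                         target_snr = Inf, fs = cfg$fs),
                     band = cfg$band, order = cfg$order)
    utils::write.csv(tab, p("sweep.csv"), row.names = FALSE)
    files <- c(files, sweep = p("sweep.csv"))
  } else if (recipe == "roc_sweep") {
    rows <- list()
    for (snr in cfg$snr_grid) for (k in seq_len(cfg$n_seeds)) {
      sim <- assemble_signal(sim_config(rate = cfg$rate,
                                        duration = cfg$duration,
                                        width_hh_ms = cfg$width_hh_ms,
                                        target_snr = snr, fs = cfg$fs,
                                        seed = cfg$seed + k))
      nlp <- design_filter(filter_spec("NLP", "butterworth", cfg$order,
                                       cfg$band, cfg$fs))
      for (cl in c("NLP", "ZP")) {
        sigf <- if (cl == "NLP") apply_causal(sim$signal, nlp) else
          apply_zero_phase(sim$signal, nlp)
        err <- detection_error(roc(sigf, sim$train))
        rows[[length(rows) + 1L]] <-
          data.frame(snr = snr, seed = cfg$seed + k, phase_class = cl,
                     detection_error = err)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, p("detection_errors.csv"), row.names = FALSE)
    files <- c(files, errors = p("detection_errors.csv"))
  } else if (recipe == "continuous_correction") {
    sim <- assemble_signal(sim_config(rate = cfg$rate,
                                      duration = cfg$duration,
                                      width_hh_ms = cfg$width_hh_ms,
                                      target_snr = cfg$target_snr,
                                      fs = cfg$fs, seed = cfg$seed))
    nlp <- design_filter(filter_spec("NLP", "butterworth", cfg$order,
                                     cfg$band, cfg$fs))
    distorted <- apply_causal(sim$signal, nlp)
    corrected <- correct_continuous(distorted, nlp)
    zp <- apply_zero_phase(sim$signal, nlp)
    w <- lapply(list(raw = sim$signal, nlp = distorted, zp = zp,
                     corrected = corrected),
                mean_waveform, train = sim$train)
    wf <- data.frame(sample = seq_along(w$raw$mean),
                     raw = w$raw$mean, nlp = w$nlp$mean, zp = w$zp$mean,
                     corrected = w$corrected$mean)
    utils::write.csv(wf, p("mean_waveforms.csv"), row.names = FALSE)
    save_signal(corrected, p("corrected.f32"))
    save_events(sim$train, p("truth_events.csv"))
    metrics <- list(
      D_raw_nlp = normalized_distance(w$raw, w$nlp),
      D_raw_zp = normalized_distance(w$raw, w$zp),
      D_raw_corrected = normalized_distance(w$raw, w$corrected),
      D_zp_corrected = normalized_distance(w$zp, w$corrected),
      config = cfg)
    write_json_report(metrics, p("metrics.json"))
    files <- c(files, waveforms = p("mean_waveforms.csv"),
               metrics = p("metrics.json"))
  } else if (recipe == "segment_correction") {
    tab <- run_sweep("segment", cfg$segment_widths_ms, seeds = cfg$seed,
                     config = sim_config(rate = cfg$rate,
                                         duration = cfg$duration,
                                         width_hh_ms = cfg$width_hh_ms,
                                         target_snr = Inf, fs = cfg$fs),
                     band = cfg$band, order = cfg$order)
    utils::write.csv(tab, p("segment_sweep.csv"), row.names = FALSE)
    files <- c(files, sweep = p("segment_sweep.csv"))
  }
  log_line(con, "done", list(files = as.list(files)))
  invisible(as.list(files))
}

# --- command-line entry point -------------------------------------------

parse_cli_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[gsub("-", "_", key)]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out[[gsub("-", "_", key)]] <- TRUE
        i <- i + 1L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

num2 <- function(s) as.numeric(strsplit(s, ",")[[1L]])

cli_filter_spec <- function(o, fs) {
  phase <- toupper(if (is.null(o$phase_class)) "nlp" else o$phase_class)
  fam <- if (phase == "LP") "fir_hamming" else "butterworth"
  ord <- as.integer(if (is.null(o$order)) if (fam == "butterworth") 4L else 20L
                    else o$order)
  band <- if (is.null(o$band)) c(300, 6000) else num2(o$band)
  filter_spec(phase, fam, ord, band, fs)
}

#' Command-line interface
#'
#' Dispatcher for `Rscript -e 'spikephase::spikephase_cli()' -- <cmd> ...`
#' (or the installed `exec/spikephase` script). Subcommands: `simulate`,
#' `filter`, `response`, `measure`, `detect`, `roc`, `correct`, `sweep`,
#' `experiment`.
#'
#' @param args character vector of command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the subcommand's result; called for its side
#'   effects (files written, text printed).
#' @export
spikephase_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: spikephase <simulate|filter|response|measure|detect|roc|",
        "correct|sweep|experiment> [--options]\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[1L]
  o <- parse_cli_args(args[-1L])
  getn <- function(name, default) {
    if (is.null(o[[name]])) default else as.numeric(o[[name]])
  }
  res <- switch(cmd,
    simulate = {
      cfg <- sim_config(rate = getn("rate", 10),
                        duration = getn("duration", 10),
                        width_hh_ms = getn("width_ms", 0.4),
                        target_snr = getn("snr", 2.7),
                        fs = getn("fs", 44000),
                        seed = as.integer(getn("seed", 1)))
      sim <- assemble_signal(cfg)
      prefix <- if (is.null(o$out)) "sim" else o$out
      save_signal(sim$signal, paste0(prefix, "_signal.f32"))
      save_events(sim$train, paste0(prefix, "_truth.csv"))
      writeLines(c("sample", sprintf("%.17g", sim$template$samples)),
                 paste0(prefix, "_template.csv"))
      message("wrote ", prefix, "_{signal.f32,truth.csv,template.csv}")
      sim
    },
    filter = {
      sig <- load_signal(o$`in`)
      fr <- design_filter(cli_filter_spec(o, sig$fs))
      out <- apply_filter(sig, fr)
      save_signal(out, o$out)
      out
    },
    response = {
      spec <- load_filter_config(o$spec)
      fr <- design_filter(spec)
      fgrid <- seq(10, spec$fs / 2 - 10, by = 10)
      tab <- data.frame(freq_hz = fgrid,
                        magnitude = Mod(freq_response(fr, fgrid)),
                        phase_rad = phase_response(fr, fgrid),
                        group_delay_samples = group_delay(fr, fgrid))
      utils::write.csv(tab, o$out, row.names = FALSE)
      tab
    },
    measure = {
      sig <- load_signal(o$signal)
      train <- load_events(o$events,
                           duration = length(sig$samples) / sig$fs)
      win <- if (is.null(o$window_ms)) c(0.5, 1.5) else num2(o$window_ms)
      w <- mean_waveform(sig, train, win)
      sigma <- estimate_noise_std(sig, train)
      rec <- dft_reconstruct(w, min(8L, length(w$mean) %/% 2L))
      rep <- list(n_spikes = w$n_spikes, snr = snr_of(w, sigma),
                  noise_sd = sigma,
                  recon_energy_fraction =
                    sum(rec^2) / sum((w$mean - mean(w$mean))^2))
      if (!is.null(o$reference)) {
        ref <- utils::read.csv(o$reference)[[1L]]
        rep$distance <- normalized_distance(ref, w$mean)
      }
      write_json_report(rep, o$out)
      rep
    },
    detect = {
      sig <- load_signal(o$signal)
      det <- detect_threshold(sig, getn("threshold", NA),
                              dead_time_ms = getn("dead-time-ms", 1))
      save_events(det, o$out)
      det
    },
    roc = {
      sig <- load_signal(o$signal)
      truth <- load_events(o$truth,
                           duration = length(sig$samples) / sig$fs)
      rc <- roc(sig, truth)
      utils::write.csv(data.frame(threshold = rc$thresholds,
                                  alpha = rc$alpha,
                                  one_minus_beta = rc$tpr),
                       o$out, row.names = FALSE)
      write_json_report(list(detection_error = detection_error(rc)),
                        paste0(o$out, ".summary.json"))
      rc
    },
    correct = {
      fr <- design_filter(load_filter_config(o$filter_spec))
      if (identical(o$mode, "segments")) {
        segs <- load_segments(o$segments)
        mode <- if (is.null(o$expansion)) "linear" else o$expansion
        out <- correct_segments(segs, fr, mode,
                                pad_ms = if (is.null(o$pad_ms)) NULL else
                                  as.numeric(o$pad_ms))
        save_segments(out, o$out)
        out
      } else {
        sig <- load_signal(o$signal)
        out <- correct_continuous(sig, fr)
        save_signal(out, o$out)
        out
      }
    },
    sweep = {
      vary <- o$vary
      grid <- num2(o$grid)
      seeds <- as.integer(num2(if (is.null(o$seeds)) "1" else o$seeds))
      tab <- run_sweep(vary, grid, seeds)
      utils::write.csv(tab, o$out, row.names = FALSE)
      tab
    },
    experiment = {
      run_experiment(o$positional[1L],
                     out_dir = if (is.null(o$out_dir)) "." else o$out_dir,
                     seed = as.integer(getn("seed", 1)))
    },
    stop("unknown subcommand '", cmd, "'")
  )
  invisible(res)
}
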