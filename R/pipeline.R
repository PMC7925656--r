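#' Default pipeline configuration
#'
#' A nested, fully serializable list describing one simulated session and
#' its analysis: stimulation protocol, traveling-wave and noise models,
#' preprocessing parameters, and analysis thresholds.  Every field can be
#' overridden before passing the list to [run_pipeline()].
#'
#' @param seed master seed; all randomness in the run derives from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    input_recording = NULL,          # path to .rds/.edf; NULL = simulate
    rate = 2048,
    montage_file = NULL,             # NULL = built-in 32-channel 10-20
    protocol = list(frequencies = c(40, 42, 44, 46, 48, 52, 54, 56, 58, 60),
                    trials_per_condition = 10, stim_duration = 2,
                    isi_range = c(3, 6), duty_cycle = 0.5,
                    modulation_depth = 1.0),
    wave = list(source = "Pz", v0 = 8.6, v_slope = 0.24, f_ref = 40,
                amplitude = 4, amplitude_decay = 10, onset_latency = 0.1,
                onset_ramp = 0.15),
    noise = list(background_exponent = 1, background_rms = 15,
                 line_freq = 50, line_rms = 10, spatial_scale = 0),
    preprocess = list(notch_freq = 50, notch_q = 45, target_rate = 256,
                      spatial_filter = "laplacian", window = c(-1, 3)),
    analysis = list(plv_threshold = 0.5, pls_threshold = 0.05,
                    n_surrogates = 200, source_override = "Pz",
                    subset = gradient_electrodes(),
                    window_centers = seq(0.25, 1.75, by = 0.25),
                    n_cycles = 5, folding_factor = 1,
                    run_ers = TRUE, run_pls = TRUE)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a pipeline configuration before any computation
#' @param config configuration list (see [default_config()]).
#' @return the config, invisibly; errors on inconsistency.
#' @export
validate_config <- function(config) {
  m <- if (is.null(config$montage_file)) default_montage()
       else load_montage(config$montage_file)
  bad <- setdiff(config$analysis$subset, m$name)
  if (length(bad))
    stop("config error: unknown electrode(s) in analysis subset: ",
         paste(bad, collapse = ", "))
  if (!is.null(config$analysis$source_override) &&
      !config$analysis$source_override %in% m$name)
    stop("config error: unknown source_override channel")
  if (is.null(config$input_recording) &&
      !(config$wave$source %in% m$name))
    stop("config error: wave source not in montage")
  sf <- config$preprocess$spatial_filter
  if (!sf %in% c("laplacian", "car", "none"))
    stop("config error: spatial_filter must be laplacian|car|none")
  fr <- config$protocol$frequencies
  if (any(fr + 3 >= config$preprocess$target_rate / 2))
    stop("config error: stimulation band reaches the decimated Nyquist")
  invisible(config)
}

.cfg_protocol <- function(p) do.call(stim_protocol, p)
.cfg_wave <- function(w) do.call(wave_model, w)
.cfg_noise <- function(n) do.call(noise_model, n)

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation with the configured
#' ground truth, or loading a recording), preprocessing (notch ->
#' downsample -> spatial filter -> epoching), per-condition ERS maps,
#' stimulus-locked PLV/PLS with locking delays and source selection, and
#' per-condition phase-velocity estimation with the velocity-frequency
#' trend.  Identical config + seed give identical outputs.
#'
#' @param config configuration list, see [default_config()].
#' @param seed overrides `config$seed` when given.
#' @param outdir optional directory; when given, result tables (TSV),
#'   a JSON summary, the effective config (YAML) and a run manifest are
#'   written there.
#' @param verbose emit stage messages.
#' @return an object of class `ssvep_run`: the recording's events, ERS
#'   tables, PLV/PLS summaries, locking delays, the selected (and any
#'   pinned) source, the `ssvep_velocity` estimate and the trend fit.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         outdir = NULL, verbose = FALSE) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  m <- if (is.null(config$montage_file)) default_montage()
       else load_montage(config$montage_file)
  if (is.null(config$input_recording)) {
    say("stage simulate: seed %d", config$seed)
    rec <- simulate_recording(.cfg_protocol(config$protocol),
                              .cfg_wave(config$wave),
                              .cfg_noise(config$noise),
                              m, rate = config$rate, seed = config$seed)
  } else {
    say("stage load: %s", config$input_recording)
    rec <- if (grepl("\\.edf$", config$input_recording, ignore.case = TRUE))
      read_edf(config$input_recording)
    else read_recording(config$input_recording)
  }
  pp <- config$preprocess
  say("stage preprocess")
  epochs <- tryCatch(
    preprocess(rec, m, notch_freq = pp$notch_freq, notch_q = pp$notch_q,
               target_rate = pp$target_rate,
               spatial_filter = pp$spatial_filter, window = pp$window,
               verbose = verbose),
    error = function(e) stop("stage preprocess failed: ",
                             conditionMessage(e)))
  an <- config$analysis
  ers <- NULL
  if (isTRUE(an$run_ers)) {
    say("stage ers")
    ers <- lapply(epochs, function(ep) ers_map(stft_power(ep)))
  }
  delays <- NULL; plv_tabs <- NULL; source_selected <- NULL
  if (isTRUE(an$run_pls)) {
    say("stage phase-sync: %d surrogates per condition", an$n_surrogates)
    plv_tabs <- list()
    dl <- list()
    for (i in seq_along(epochs)) {
      key <- names(epochs)[i]
      pv <- condition_plv(epochs, key, n_surrogates = an$n_surrogates,
                          seed = config$seed + 1000L + i)
      dl[[key]] <- locking_delay(pv, an$plv_threshold, an$pls_threshold)
      plv_tabs[[key]] <- pv
    }
    delays <- do.call(rbind, dl)
    source_selected <- select_source(delays, m)
    say("data-driven source: %s", source_selected)
  }
  source_used <- if (!is.null(an$source_override)) an$source_override
                 else source_selected
  if (is.null(source_used))
    stop("no source available: enable run_pls or set source_override")
  say("stage velocity: source %s", source_used)
  vel <- estimate_velocity(epochs, m, source = source_used,
                           subset = an$subset,
                           window_centers = an$window_centers,
                           n_cycles = an$n_cycles,
                           folding_factor = an$folding_factor)
  res <- structure(list(config = config, events = rec$events,
                        montage = m, ers = ers, plv = plv_tabs,
                        delays = delays, source_selected = source_selected,
                        source_used = source_used, velocity = vel,
                        trend = vel$trend),
                   class = "ssvep_run")
  if (!is.null(outdir)) .write_run(res, outdir)
  res
}

#' @export
print.ssvep_run <- function(x, ...) {
  cat("<ssvep_run>\n")
  cat(sprintf("  events: %d | source used: %s%s\n", nrow(x$events),
              x$source_used,
              if (!is.null(x$source_selected))
                sprintf(" (data-driven: %s)", x$source_selected) else ""))
  print(x$velocity)
  invisible(x)
}

.write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$velocity$table, "velocity.tsv")
  if (!is.null(res$delays)) {
    dd <- data.frame(condition = rep(rownames(res$delays),
                                     ncol(res$delays)),
                     channel = rep(colnames(res$delays),
                                   each = nrow(res$delays)),
                     delay_s = as.vector(res$delays))
    wt(dd, "locking_delays.tsv")
  }
  if (!is.null(res$ers)) {
    ee <- do.call(rbind, lapply(names(res$ers), function(k) {
      df <- as.data.frame(res$ers[[k]])
      cbind(condition = k, df)
    }))
    wt(ee, "ers.tsv")
  }
  summ <- list(source_used = res$source_used,
               source_selected = res$source_selected,
               trend = res$trend,
               velocity_range = range(res$velocity$table$velocity),
               wavelength_range = range(res$velocity$table$wavelength))
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config(res$config, file.path(outdir, "config.yaml"))
  manifest <- list(
    package = "ssvepwave",
    version = as.character(utils::packageVersion("ssvepwave")),
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
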