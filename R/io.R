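# Formats, configuration and the end-to-end pipeline driver.

#' Write / read a gaze trace TSV
#'
#' Columns `time_ms`, `x`, `y`; the coordinate unit (`"px"` or `"deg"`) is
#' recorded in a `# unit:` header comment and restored on read.
#'
#' @param trace Gaze trace data.frame (attribute `unit`).
#' @param path File path.
#' @export
write_gaze <- function(trace, path) {
  con <- file(path, "w")
  writeLines(sprintf("# unit: %s", attr(trace, "unit") %||% "px"), con)
  utils::write.table(trace, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  first <- readLines(path, n = 1)
  unit <- if (grepl("^# unit:", first)) trimws(sub("^# unit:", "", first)) else "px"
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  attr(out, "unit") <- unit
  out
}

# ---------------------------------------------------------------------------
# Minimal BrainVision-compatible continuous EEG I/O (text .vhdr/.vmrk plus
# IEEE float32 multiplexed binary .eeg). Only the fields this pipeline needs
# are written/parsed.

#' Write a recording in BrainVision format
#'
#' @param rec An `eeg_recording`.
#' @param basename Path without extension; writes `.vhdr`, `.vmrk`, `.eeg`.
#' @export
write_brainvision <- function(rec, basename) {
  nch <- ncol(rec$data)
  vhdr <- c("Brain Vision Data Exchange Header File Version 1.0",
            "", "[Common Infos]",
            sprintf("DataFile=%s.eeg", basename(basename)),
            sprintf("MarkerFile=%s.vmrk", basename(basename)),
            "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
            sprintf("NumberOfChannels=%d", nch),
            sprintf("SamplingInterval=%d", round(1e6 / rec$sfreq)),
            "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
            "", "[Channel Infos]",
            sprintf("Ch%d=%s,,1,uV", seq_len(nch), rec$ch_names))
  writeLines(vhdr, paste0(basename, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]",
               sprintf("DataFile=%s.eeg", basename(basename)),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
  close(con)
  invisible(basename)
}

#' @rdname write_brainvision
#' @param montage Optional montage to attach on read (matched by channel
#'   name when given).
#' @export
read_brainvision <- function(basename, montage = NULL) {
  hdr <- readLines(paste0(basename, ".vhdr"))
  val <- function(key) sub(paste0("^", key, "="), "",
                           grep(paste0("^", key, "="), hdr, value = TRUE)[1])
  nch <- as.integer(val("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(val("SamplingInterval"))
  chl <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", chl), ","),
                     `[[`, character(1), 1)
  stopifnot(identical(val("BinaryFormat"), "IEEE_FLOAT_32"),
            identical(val("DataOrientation"), "MULTIPLEXED"))
  con <- file(paste0(basename, ".eeg"), "rb")
  raw <- readBin(con, numeric(), n = file.size(paste0(basename, ".eeg")) / 4,
                 size = 4, endian = "little")
  close(con)
  data <- matrix(raw, ncol = nch, byrow = TRUE)
  colnames(data) <- ch_names
  if (is.null(montage)) {
    full <- standard_montage("full")
    montage <- full[match(ch_names, full$channel), , drop = FALSE]
  }
  structure(list(data = data, sfreq = sfreq, montage = montage,
                 ch_names = ch_names,
                 ch_types = montage$type %||% rep("eeg", nch), t0_ms = 0),
            class = "eeg_recording")
}

# ---------------------------------------------------------------------------
# Configuration and the end-to-end driver

#' Default pipeline configuration
#'
#' Nested list holding every tunable parameter of the pipeline with its
#' study value (thresholds, windows, band, subsample count, alpha, decision
#' fraction), plus the simulation scale. The default scale is a demonstration
#' cohort (8 participants, one 36-trial run, 16-channel layout) so that the
#' end-to-end driver runs in minutes; the full study scale is 19-20
#' participants, four 84-trial runs and the 64-channel layout.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cohort = list(n_participants = 8, n_runs = 1, trials_per_run = 36,
                  montage = "small"),
    paradigm = list(fixation_choices = FIXATION_CHOICES),
    geometry = list(width_px = 1280, height_px = 1024, diagonal_in = 17,
                    distance_cm = 60, target_offset_deg = 8.30,
                    center_threshold_deg = 4.04),
    detection = list(min_center_distance_deg = 4.04,
                     min_horizontal_amplitude_deg = 4.04,
                     min_duration_ms = 15, vertical_fraction = 0.80),
    behavior = list(error_prob = c(pro = 0.0521, anti = 0.0521, nogo = 0.0521)),
    eeg = list(l_freq = 0.05, h_freq = 45, resample_to = 500,
               reject_ptp_uv = 150,
               ern_window_ms = c(70, 160), pe_window_ms = c(200, 500),
               theta_band = c(4, 8)),
    effects = list(theta_db = c(pre_correct = 1.58, pre_error = 1.26,
                                post_correct = 1.35, post_error = 2.31)),
    stats = list(k_subsamples = 20, alpha = 0.05, required_fraction = 0.80,
                 match_pro_proportion = TRUE),
    out_dir = "results/pipeline")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return Configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  modifyList(default_config(), usr)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# one global seed fanned out to per-stage sub-seeds
derive_seeds <- function(seed, n = 8) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(1e6, n)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulate -> detect -> classify -> preprocess/epoch/power -> replication
#' stats, writing all stage outputs (TSV) and a JSON run manifest to
#' `config$out_dir`. Deterministic given `config$seed`.
#'
#' @param config A configuration list (see [default_config()]) or a path to
#'   a YAML file.
#' @return The run manifest (invisibly also written as
#'   `manifest.json`): config snapshot, seeds, per-stage output digests,
#'   warnings.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, n = 4 + config$cohort$n_participants)
  geom <- do.call(screen_geometry, config$geometry)
  det <- do.call(detection_params, config$detection)
  pcfg <- preproc_config(l_freq = config$eeg$l_freq, h_freq = config$eeg$h_freq,
                         resample_to = config$eeg$resample_to,
                         reject_ptp_uv = config$eeg$reject_ptp_uv)
  ecfg <- eeg_effect_config(theta_db = config$effects$theta_db)
  bmod <- behavior_model(error_prob = config$behavior$error_prob)
  montage <- standard_montage(config$cohort$montage)
  warnings <- character()

  all_trials <- list(); all_theta <- list(); all_summ <- list()
  for (i in seq_len(config$cohort$n_participants)) {
    pid <- sprintf("p%02d", i)
    pseed <- seeds[4 + i]
    session <- generate_session(pseed, config$cohort$n_runs,
                                config$cohort$trials_per_run)
    gz <- simulate_gaze(session, bmod, geom, seed = pseed + 1)
    rec <- simulate_eeg(session, gz$truth, ecfg, seed = pseed + 2,
                        montage = montage)
    events <- detect_events(to_degrees(gz$trace, geom), det)
    trials <- build_trial_records(session, events, participant = pid)
    clean <- preprocess(rec, pcfg)
    eps <- withCallingHandlers(
      epoch_around_saccades(clean, trials, session, pcfg),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    th <- theta_power(eps, clean, "FCz", config$eeg$theta_band)
    all_trials[[pid]] <- trials
    all_theta[[pid]] <- th
    all_summ[[pid]] <- summarize_behavior(trials, pid)
  }
  trials <- do.call(rbind, all_trials)
  theta <- do.call(rbind, all_theta)
  summ <- do.call(rbind, all_summ)

  rep_cfg <- replication_config(config$stats$k_subsamples, config$stats$alpha,
                                config$stats$required_fraction,
                                config$stats$match_pro_proportion,
                                seed = seeds[2])
  run_rep <- function(seg) {
    tryCatch(withCallingHandlers(
      replication_test(theta[theta$segment == seg, ], "power_db", rep_cfg),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        warnings <<- c(warnings, conditionMessage(e))
        NULL
      })
  }
  rep_pre <- run_rep("pre"); rep_post <- run_rep("post")

  paths <- c(trials = "trial_records.tsv", theta = "theta_power.tsv",
             behavior = "behavior_summary.tsv",
             decisions = "theta_decisions.tsv")
  wt <- function(x, f) utils::write.table(x, file.path(config$out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(trials, paths["trials"]); wt(theta, paths["theta"])
  wt(summ, paths["behavior"])
  dec <- do.call(rbind, lapply(list(pre = rep_pre, post = rep_post), function(r)
    if (is.null(r)) data.frame(mean_z = NA, sd_z = NA, n_sig = NA,
                               required = NA, decision = NA, mean_r = NA)
    else data.frame(mean_z = r$mean_z, sd_z = r$sd_z, n_sig = r$n_sig,
                    required = r$required, decision = r$decision,
                    mean_r = r$mean_r)))
  dec <- cbind(segment = rownames(dec), dec)
  wt(dec, paths["decisions"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("errtheta")),
    config = config, seeds = seeds, warnings = unique(warnings),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, paths))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
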