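# Segment-level theta simulation: generates, at the analysis sampling rate,
# exactly the three signal segments the theta measure consumes per epoch
# (Gap baseline 250 ms, pre-response 500 ms, post-response 500 ms), runs the
# package's Welch band-power estimator on them, and feeds the resulting
# per-trial dB values into the replication machinery. This bypasses the
# continuous-recording plumbing (filtering, epoching), which is validated
# separately end-to-end, and makes many-replicate power and type-I studies
# tractable on one CPU.

#' Simulate per-epoch theta dB estimates for one participant
#'
#' Each epoch gets a Gap-baseline segment (theta carrier at baseline
#' amplitude plus 1/f background), and pre/post segments whose carrier
#' amplitude realises the configured cell dB (plus per-segment jitter).
#' The returned dB values are computed by the same estimator the full
#' pipeline uses ([band_power_welch()] and the 10 log10 ratio), at the
#' analysis rate of 500 Hz.
#'
#' @param n_epochs Retained (response-locked) epochs for this participant.
#' @param cfg An [eeg_effect_config()] (cells, carrier, noise ratios).
#' @param error_prob Probability that an epoch is an error trial (error
#'   epochs are pro with probability 1/3, correct epochs with 1/2,
#'   reflecting the paradigm's class mix among response-locked trials).
#' @param participant Identifier.
#' @param participant_shift_db A constant added to all four cells (between-
#'   participant baseline heterogeneity; cancels in paired contrasts).
#' @param fs Analysis sampling rate.
#' @return Data.frame: `participant`, `trial`, `outcome`, `trial_class`,
#'   `segment`, `power_db` (one pre and one post row per epoch).
#' @export
simulate_theta_epochs <- function(n_epochs, cfg = eeg_effect_config(),
                                  error_prob = 0.06, participant = "p01",
                                  participant_shift_db = 0, fs = 500) {
  a0 <- cfg$theta_amplitude_uv
  gap_len <- round(0.25 * fs); seg_len <- round(0.5 * fs)
  kappa_gap <- band_capture(cfg$theta_freq_hz, fs, gap_len)
  kappa_seg <- band_capture(cfg$theta_freq_hz, fs, seg_len)
  b_band <- cfg$bg_band_ratio * kappa_gap * a0^2 / 2
  frac_gap <- pink_band_fraction(gap_len, fs, cfg$bg_exponent)
  frac_seg <- pink_band_fraction(seg_len, fs, cfg$bg_exponent)
  sd_gap <- sqrt(b_band / frac_gap); sd_seg <- sqrt(b_band / frac_seg)

  is_err <- stats::runif(n_epochs) < error_prob
  outcome <- ifelse(is_err, "error", "correct")
  is_pro <- stats::runif(n_epochs) < ifelse(is_err, 1 / 3, 1 / 2)
  cls <- ifelse(is_pro, "pro",
                ifelse(is_err & stats::runif(n_epochs) < 0.5, "nogo", "anti"))
  d_pre <- cfg$theta_db[paste0("pre_", outcome)] + participant_shift_db +
    stats::rnorm(n_epochs, 0, cfg$trial_jitter_db)
  d_post <- cfg$theta_db[paste0("post_", outcome)] + participant_shift_db +
    stats::rnorm(n_epochs, 0, cfg$trial_jitter_db)

  make_seg <- function(len, sd_bg, amps) {
    tt <- seq_len(len) / fs
    ph <- stats::runif(n_epochs, 0, 2 * pi)
    carrier <- sin(outer(tt * 2 * pi * cfg$theta_freq_hz, ph, "+"))
    noise <- pink_noise(len, n_epochs, fs, cfg$bg_exponent, sd = sd_bg)
    carrier * rep(amps, each = len) + noise
  }
  gap <- make_seg(gap_len, sd_gap, rep(a0, n_epochs))
  pre <- make_seg(seg_len, sd_seg,
                  planted_amplitude(d_pre, a0, kappa_seg, kappa_gap, b_band))
  post <- make_seg(seg_len, sd_seg,
                   planted_amplitude(d_post, a0, kappa_seg, kappa_gap, b_band))
  p_gap <- band_power_welch(gap, fs)
  db_pre <- 10 * log10(band_power_welch(pre, fs) / p_gap)
  db_post <- 10 * log10(band_power_welch(post, fs) / p_gap)
  data.frame(participant = participant, trial = seq_len(n_epochs),
             outcome = outcome, trial_class = cls,
             segment = rep(c("pre", "post"), each = n_epochs),
             power_db = c(db_pre, db_post), stringsAsFactors = FALSE)
}

#' One simulated theta study (cohort) with replication tests
#'
#' Simulates `n_participants` participants' per-epoch theta dB values and
#' runs the balanced replication test on the pre- and post-response
#' segments.
#'
#' @param n_participants Cohort size.
#' @param n_epochs Epochs per participant.
#' @param cfg An [eeg_effect_config()].
#' @param error_prob Per-epoch error probability.
#' @param between_sd_db SD of the participant baseline shift, dB.
#' @param seed Integer seed.
#' @param rep_cfg A [replication_config()] (its seed is overridden from
#'   `seed`).
#' @return List with `trials` (stacked per-epoch table), `cell_means`
#'   (named: `pre_correct`, `pre_error`, `post_correct`, `post_error`,
#'   means over participant cell means), `pre` and `post`
#'   ([replication_test()] results).
#' @export
theta_study <- function(n_participants = 19, n_epochs = 200,
                        cfg = eeg_effect_config(), error_prob = 0.06,
                        between_sd_db = 0.3, seed = 1,
                        rep_cfg = replication_config()) {
  set.seed(as.integer(seed))
  shifts <- stats::rnorm(n_participants, 0, between_sd_db)
  trials <- do.call(rbind, lapply(seq_len(n_participants), function(i)
    simulate_theta_epochs(n_epochs, cfg, error_prob,
                          participant = sprintf("p%02d", i),
                          participant_shift_db = shifts[i])))
  # participant-level cell means, then cohort means
  agg <- stats::aggregate(power_db ~ participant + outcome + segment,
                          trials, mean)
  cell <- function(seg, out) mean(agg$power_db[agg$segment == seg &
                                                 agg$outcome == out])
  cells <- c(pre_correct = cell("pre", "correct"),
             pre_error = cell("pre", "error"),
             post_correct = cell("post", "correct"),
             post_error = cell("post", "error"))
  rep_cfg$seed <- as.integer(seed) + 1L
  pre <- suppressWarnings(
    replication_test(trials[trials$segment == "pre", ], "power_db", rep_cfg))
  post <- suppressWarnings(
    replication_test(trials[trials$segment == "post", ], "power_db", rep_cfg))
  list(trials = trials, cell_means = cells, pre = pre, post = post)
}

#' Replicated theta power study
#'
#' Repeats [theta_study()] `n_replicates` times with derived seeds and
#' tallies how often the planted cell ordering (pre-correct > pre-error;
#' post-error > post-correct) is recovered and how often the replication
#' decision is significant for each contrast.
#'
#' @inheritParams theta_study
#' @param n_replicates Number of independent simulated cohorts.
#' @return List with per-replicate logicals `ordering_ok`, `pre_sig`,
#'   `post_sig` and the summary rates.
#' @export
theta_power_study <- function(n_replicates = 100, n_participants = 19,
                              n_epochs = 200, cfg = eeg_effect_config(),
                              error_prob = 0.06, seed = 1) {
  res <- lapply(seq_len(n_replicates), function(rr) {
    st <- theta_study(n_participants, n_epochs, cfg, error_prob,
                      seed = as.integer(seed) + 1000L + rr)
    c(ordering_ok = unname(st$cell_means["pre_correct"] > st$cell_means["pre_error"] &&
                           st$cell_means["post_error"] > st$cell_means["post_correct"]),
      pre_sig = st$pre$decision, post_sig = st$post$decision)
  })
  res <- as.data.frame(do.call(rbind, res))
  list(replicates = res,
       ordering_rate = mean(res$ordering_ok),
       pre_sig_rate = mean(res$pre_sig),
       post_sig_rate = mean(res$post_sig))
}

#' Type-I error of the full replication decision under the null
#'
#' Runs [theta_study()] with all four theta cells equal (no planted
#' difference) and reports how often the aggregate >=16-of-20 decision
#' fires for either contrast.
#'
#' @inheritParams theta_power_study
#' @param null_db The common cell value, dB.
#' @return List with the per-contrast false-positive rates and replicate
#'   table.
#' @export
theta_type1_study <- function(n_replicates = 500, n_participants = 19,
                              n_epochs = 50, null_db = 1.5, seed = 1,
                              cfg = eeg_effect_config()) {
  cfg$theta_db[] <- null_db
  res <- lapply(seq_len(n_replicates), function(rr) {
    st <- theta_study(n_participants, n_epochs, cfg,
                      seed = as.integer(seed) + 5000L + rr)
    c(pre_sig = st$pre$decision, post_sig = st$post$decision)
  })
  res <- as.data.frame(do.call(rbind, res))
  list(replicates = res,
       pre_rate = mean(res$pre_sig),
       post_rate = mean(res$post_sig))
}
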