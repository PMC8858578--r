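test_that("segment-level epoch simulation is deterministic and calibrated", {
  set.seed(1)
  a <- simulate_theta_epochs(100)
  set.seed(1)
  b <- simulate_theta_epochs(100)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)  # pre + post row per epoch
  # a null configuration centres the estimates on 0 dB
  cfg0 <- eeg_effect_config(theta_db = c(pre_correct = 0, pre_error = 0,
                                         post_correct = 0, post_error = 0),
                            trial_jitter_db = 0)
  set.seed(2)
  null <- simulate_theta_epochs(400, cfg0)
  expect_equal(mean(null$power_db), 0, tolerance = 0.1)
  # planted cells are recovered near their nominal values
  set.seed(3)
  big <- simulate_theta_epochs(600, error_prob = 0.5)
  for (seg in c("pre", "post")) for (out in c("correct", "error")) {
    m <- mean(big$power_db[big$segment == seg & big$outcome == out])
    expect_equal(m, unname(eeg_effect_config()$theta_db[paste0(seg, "_", out)]),
                 tolerance = 0.2)
  }
})

test_that("a single simulated cohort recovers ordering and significance", {
  st <- theta_study(n_participants = 19, n_epochs = 200, seed = 8)
  cm <- st$cell_means
  expect_gt(cm[["pre_correct"]], cm[["pre_error"]])
  expect_gt(cm[["post_error"]], cm[["post_correct"]])
  expect_s3_class(st$pre, "replication_result")
  expect_equal(st$pre$n_participants, 19)
  # the pre contrast is negative (error below correct), the post positive
  expect_lt(st$pre$mean_z, 0)
  expect_gt(st$post$mean_z, 0)
})

test_that("planted cell differences move only the theta part of the spectrum", {
  # error and correct trials share everything except the post theta cell;
  # their average post-window FCz spectra must differ only within 4-8 Hz
  s <- generate_session(91, 1, 48)
  m <- behavior_model(noise_sd_deg = 0.02, no_response_prob = 0,
                      error_prob = c(pro = 0.5, anti = 0.5, nogo = 0.5))
  gz <- simulate_gaze(s, m, seed = 25)
  cfg <- eeg_effect_config(theta_db = c(pre_correct = 0, pre_error = 0,
                                        post_correct = 0, post_error = 5),
                           trial_jitter_db = 0, ocular_gain = 0)
  rec <- simulate_eeg(s, gz$truth, cfg, seed = 26,
                      montage = standard_montage("small"))
  fs <- rec$sfreq
  oc <- gz$truth$outcomes
  grab <- function(out) {
    on <- oc$true_onset_ms[oc$outcome == out]
    sapply(on, function(t0) {
      i0 <- round(t0 / 1000 * fs) + 1
      rec$data[i0:(i0 + round(fs / 2) - 1), "FCz"]
    })
  }
  p_err <- rowMeans(welch_psd(grab("error"), fs, window_sec = 0.25)$psd)
  p_cor <- rowMeans(welch_psd(grab("correct"), fs, window_sec = 0.25)$psd)
  freq <- welch_psd(matrix(0, round(fs / 2)), fs, 0.25)$freq
  ratio_db <- 10 * log10(p_err / p_cor)
  inb <- freq >= 4 & freq <= 8
  # past the estimator mainlobe (+/- 8 Hz around the 6 Hz carrier): clean
  out <- freq > 16 & freq <= 45
  expect_gt(max(ratio_db[inb]), 3)              # the planted excess shows up
  # individual out-of-band bins carry little power and hence noisy ratios;
  # any systematic elevation would show in their mean, which must sit at 0 dB
  expect_lt(abs(mean(ratio_db[out])), 0.75)     # and only around the theta band
})

test_that("replicated power and type-I studies report rates", {
  ps <- theta_power_study(n_replicates = 4, n_participants = 8, n_epochs = 60,
                          seed = 5)
  expect_equal(nrow(ps$replicates), 4)
  expect_true(all(c("ordering_rate", "pre_sig_rate", "post_sig_rate")
                  %in% names(ps)))
  t1 <- theta_type1_study(n_replicates = 4, n_participants = 8, n_epochs = 30,
                          seed = 6)
  expect_true(t1$pre_rate >= 0 && t1$pre_rate <= 1)
})
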