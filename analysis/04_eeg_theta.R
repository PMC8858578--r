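#!/usr/bin/env Rscript
# Preprocess the simulated EEG (zero-phase FIR 0.05-45 Hz, 500 Hz resample,
# average reference, automated bad-channel handling), epoch [-500, +500] ms
# around each response saccade, and extract ERN/Pe window amplitudes plus
# 4-8 Hz power in dB against the Gap-stage baseline.

library(errtheta)

cfg <- preproc_config()
files <- Sys.glob("results/cohort/p*_session.tsv")
stopifnot(length(files) > 0)

theta_all <- list(); erp_all <- list(); rej <- c()
for (f in files) {
  pid <- sub("_session.tsv", "", basename(f))
  session <- read_session(f)
  trials <- read.delim("results/trial_records.tsv")
  trials <- trials[trials$participant == pid, ]
  rec <- read_brainvision(sprintf("results/cohort/%s_eeg", pid),
                          montage = standard_montage("small"))
  clean <- preprocess(rec, cfg)
  eps <- epoch_around_saccades(clean, trials, session, cfg)
  rej[pid] <- eps$rejection_fraction
  theta_all[[pid]] <- theta_power(eps, clean, "FCz")
  erp_all[[pid]] <- data.frame(
    participant = pid, run = eps$info$run, trial = eps$info$trial,
    outcome = eps$info$outcome, trial_class = eps$info$trial_class,
    ern_uv = erp_mean_amplitude(eps, "FCz", c(70, 160)),
    pe_uv = erp_mean_amplitude(eps, "Pz", c(200, 500)))
}
theta <- do.call(rbind, theta_all)
erp <- do.call(rbind, erp_all)
write.table(theta, "results/theta_power.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(erp, "results/erp_amplitudes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cells <- aggregate(power_db ~ segment + outcome, theta, mean)
print(cells)
message(sprintf("mean epoch rejection: %.2f%%", 100 * mean(rej)))
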