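#!/usr/bin/env Rscript
# Decide correct-versus-error differences with the 20-subsample balanced
# Wilcoxon replication procedure (pro-saccade proportion matched, >=16 of 20
# tests at p <= .05), on the theta dB tables and the behavioural metrics;
# report effect sizes r = Z/sqrt(N) and JZS Bayes factors for the
# non-significant contrasts. The demonstration cohort is small, so decisions
# here illustrate the machinery; the study-scale operating characteristics
# are measured by theta_power_study() / theta_type1_study() (see
# scripts/acceptance.R).

library(errtheta)

theta <- read.delim("results/theta_power.tsv")
trials <- read.delim("results/trial_records.tsv")
cfg <- replication_config(seed = 99)

run_one <- function(tab, value, label) {
  res <- tryCatch(suppressWarnings(replication_test(tab, value, cfg)),
                  error = function(e) NULL)
  if (is.null(res)) {
    message(label, ": not testable on this cohort")
    return(NULL)
  }
  message(sprintf(
    "%-12s mean Z = %6.2f +/- %.2f  r = %5.2f  %2d/%d significant -> %s",
    label, res$mean_z, res$sd_z, res$mean_r, res$n_sig,
    nrow(res$iterations), if (res$decision) "SIGNIFICANT" else "n.s."))
  data.frame(metric = label, mean_z = res$mean_z, sd_z = res$sd_z,
             mean_r = res$mean_r, n_sig = res$n_sig,
             required = res$required, decision = res$decision)
}

resp <- trials[trials$outcome %in% c("correct", "error"), ]
out <- list(
  run_one(theta[theta$segment == "pre", ], "power_db", "theta_pre"),
  run_one(theta[theta$segment == "post", ], "power_db", "theta_post"),
  run_one(transform(resp, value = response_timing_ms), "value", "timing"),
  run_one(transform(resp, value = saccade_amplitude_deg), "value", "amplitude"),
  run_one(transform(resp, value = saccade_duration_ms), "value", "duration"))
out <- do.call(rbind, out)
write.table(out, "results/replication_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# paired Bayes factor on per-participant mean response timing (the study's
# absence-of-difference check)
agg <- aggregate(response_timing_ms ~ participant + outcome, resp, mean)
wide <- merge(subset(agg, outcome == "correct"),
              subset(agg, outcome == "error"), by = "participant")
if (nrow(wide) >= 3) {
  bf <- paired_bayes_factor(wide$response_timing_ms.x, wide$response_timing_ms.y)
  message(sprintf("timing BF10 = %.2f, BF01 = %.2f (%s)",
                  bf$bf10, bf$bf01, bf$label))
}
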