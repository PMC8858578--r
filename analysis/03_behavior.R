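#!/usr/bin/env Rscript
# Classify each trial against its facial-cue instruction and summarise the
# behavioural metrics per participant (error rate, error-type fractions,
# response timing / amplitude / duration split by outcome).

library(errtheta)

geom <- screen_geometry()
files <- Sys.glob("results/cohort/p*_session.tsv")
stopifnot(length(files) > 0)

all_trials <- list(); summaries <- list()
for (f in files) {
  pid <- sub("_session.tsv", "", basename(f))
  session <- read_session(f)
  events <- read.delim(sprintf("results/cohort/%s_events.tsv", pid))
  trials <- build_trial_records(session, events, participant = pid)
  all_trials[[pid]] <- trials
  summaries[[pid]] <- summarize_behavior(trials, pid)
}
trials <- do.call(rbind, all_trials)
summ <- do.call(rbind, summaries)
write.table(trials, "results/trial_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ, "results/behavior_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("overall error rate: %.2f%%", 100 * mean(summ$error_rate)))
message(sprintf("saccade duration, correct vs error: %.1f vs %.1f ms",
                mean(summ$duration_correct_ms, na.rm = TRUE),
                mean(summ$duration_error_ms, na.rm = TRUE)))
message(sprintf("response timing, correct vs error: %.0f vs %.0f ms",
                mean(summ$timing_correct_ms, na.rm = TRUE),
                mean(summ$timing_error_ms, na.rm = TRUE)))
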