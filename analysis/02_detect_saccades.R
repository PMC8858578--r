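#!/usr/bin/env Rscript
# Detect saccades in the simulated gaze traces with the displacement
# thresholds (4.04 deg amplitude and central area, 15 ms minimum duration,
# 80% vertical rule) and score them against the planted ground truth.

library(errtheta)

geom <- screen_geometry()
params <- detection_params()
files <- Sys.glob("results/cohort/p*_gaze.tsv")
stopifnot(length(files) > 0)

scores <- lapply(files, function(f) {
  pid <- sub("_gaze.tsv", "", basename(f))
  trace <- to_degrees(read_gaze(f), geom)
  events <- detect_events(trace, params)
  write_events(events, sprintf("results/cohort/%s_events.tsv", pid))
  truth <- readRDS(sprintf("results/cohort/%s_truth.rds", pid))
  sc <- score_detection(events, truth)
  data.frame(participant = pid, n_events = nrow(events),
             n_saccades = sum(events$label == "saccade"),
             sensitivity = sc$sensitivity, precision = sc$precision)
})
scores <- do.call(rbind, scores)
write.table(scores, "results/detection_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(scores)
message(sprintf("mean sensitivity %.3f, mean precision %.3f",
                mean(scores$sensitivity), mean(scores$precision)))
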