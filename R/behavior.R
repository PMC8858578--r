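# Trial outcome classification and per-participant behavioural metrics.

#' Classify one trial from its first response saccade
#'
#' A response is correct if the first saccade follows the instruction:
#' pro-saccade trials require a saccade in the cued gaze direction,
#' anti-saccade trials in the opposite direction, and no-go trials require no
#' saccade at all. Any saccade on a no-go trial is an error. Trials without
#' any saccade (correct no-go trials, or go trials where no response was
#' made) are excluded from the response-locked analyses because the EEG
#' epochs are locked to saccade onset.
#'
#' @param emotion,gaze Instruction fields.
#' @param saccade_direction `"left"`, `"right"`, or `NA`/`NULL` for none.
#' @return `"correct"`, `"error"` or `"excluded_no_saccade"`.
#' @export
classify_trial <- function(emotion, gaze, saccade_direction) {
  if (is.null(saccade_direction) || is.na(saccade_direction))
    return("excluded_no_saccade")
  cls <- trial_class_of(emotion, gaze)
  if (cls == "nogo") return("error")
  want <- expected_response(emotion, gaze)
  if (paste0("saccade_", saccade_direction) == want) "correct" else "error"
}

#' Build per-trial records from detected events
#'
#' Joins a session's trials to the detected gaze events: picks each trial's
#' first response-eligible saccade, classifies the outcome, and extracts the
#' response metrics (timing relative to Response-stage onset, amplitude,
#' duration).
#'
#' @param session A [generate_session()] result.
#' @param events Detected events ([detect_events()]), in degrees and on the
#'   session clock.
#' @param participant Participant identifier stored in the output.
#' @return A data.frame with one row per trial: instruction fields,
#'   `outcome`, `response_timing_ms`, `saccade_amplitude_deg`,
#'   `saccade_duration_ms`, `saccade_onset_ms`, `saccade_direction`.
#' @export
build_trial_records <- function(session, events, participant = "p01") {
  rows <- lapply(seq_len(nrow(session)), function(i) {
    tr <- session[i, ]
    fs <- first_saccade_in_trial(events, tr)
    has <- !is.null(fs)
    data.frame(
      participant = participant, run = tr$run, trial = tr$trial,
      emotion = tr$emotion, gaze = tr$gaze, trial_class = tr$trial_class,
      outcome = classify_trial(tr$emotion, tr$gaze,
                               if (has) fs$direction else NA),
      response_timing_ms = if (has) fs$onset_ms - tr$response_on else NA_real_,
      saccade_amplitude_deg = if (has) fs$h_amplitude_deg else NA_real_,
      saccade_duration_ms = if (has) fs$duration_ms else NA_real_,
      saccade_onset_ms = if (has) fs$onset_ms else NA_real_,
      saccade_direction = if (has) fs$direction else NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-participant behavioural summary
#'
#' Computes the relative error rate (errors / classified trials), the
#' relative pro-/anti-/no-go error fractions (each error type divided by the
#' total number of errors; they sum to one when any error exists), and mean
#' response timing, saccade amplitude and saccade duration split by outcome.
#' Excluded (saccade-free) trials contribute to no metric. A participant
#' with zero errors gets `NA` error fractions and is flagged.
#'
#' @param trials Output of [build_trial_records()].
#' @param participant Identifier; defaults to the one in `trials`.
#' @return A one-row data.frame.
#' @export
summarize_behavior <- function(trials, participant = trials$participant[1]) {
  stopifnot(nrow(trials) >= 1)
  resp <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  err <- resp[resp$outcome == "error", , drop = FALSE]
  n_err <- nrow(err)
  frac <- function(cls) if (n_err > 0) mean(err$trial_class == cls) else NA_real_
  m <- function(col, out) {
    v <- resp[[col]][resp$outcome == out]
    if (length(v)) mean(v) else NA_real_
  }
  data.frame(
    participant = participant,
    n_trials = nrow(trials), n_responses = nrow(resp), n_errors = n_err,
    error_rate = if (nrow(trials) > 0) n_err / nrow(trials) else NA_real_,
    pro_error_fraction = frac("pro"),
    anti_error_fraction = frac("anti"),
    nogo_error_fraction = frac("nogo"),
    timing_correct_ms = m("response_timing_ms", "correct"),
    timing_error_ms = m("response_timing_ms", "error"),
    amplitude_correct_deg = m("saccade_amplitude_deg", "correct"),
    amplitude_error_deg = m("saccade_amplitude_deg", "error"),
    duration_correct_ms = m("saccade_duration_ms", "correct"),
    duration_error_ms = m("saccade_duration_ms", "error"),
    flagged = n_err == 0 || nrow(resp) == 0,
    stringsAsFactors = FALSE)
}
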