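#' errtheta: midfrontal theta error-monitoring analysis for a saccadic
#' go/no-go paradigm
#'
#' Tools to simulate and analyse a facial-cue go/no-go saccade experiment with
#' simultaneous eye tracking and EEG: paradigm generation, gaze/EEG
#' simulation with planted ground truth, displacement-threshold saccade
#' detection, behavioural classification, EEG preprocessing and theta-power
#' extraction, and a subsampled balanced Wilcoxon replication test.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Stage durations (ms). Fixation is drawn per trial from FIXATION_CHOICES.
STAGE_NAMES <- c("neutral", "gap", "instruction", "fixation", "target", "response")
STAGE_DURATIONS <- c(neutral = 1000, gap = 500, instruction = 750,
                     fixation = NA, target = 200, response = 1500)
FIXATION_CHOICES <- c(500, 600, 700, 800, 900, 1000)

#' The six facial instructions
#'
#' The task uses six instructions formed by crossing facial emotion
#' (happy/sad) with gaze direction (left/right/straight). A straight gaze
#' signals a no-go trial regardless of emotion; a happy averted face cues a
#' pro-saccade (look where the face looks) and a sad averted face cues an
#' anti-saccade (look the opposite way).
#'
#' @return A data.frame with columns `emotion`, `gaze` and the derived
#'   `trial_class` (`"pro"`, `"anti"` or `"nogo"`), one row per instruction.
#' @examples
#' instructions()
#' @export
instructions <- function() {
  ins <- expand.grid(emotion = c("happy", "sad"),
                     gaze = c("left", "right", "straight"),
                     stringsAsFactors = FALSE)
  ins$trial_class <- trial_class_of(ins$emotion, ins$gaze)
  ins[order(ins$trial_class, ins$emotion, ins$gaze), , drop = FALSE][
    , c("emotion", "gaze", "trial_class")] |> `rownames<-`(NULL)
}

#' Derive the trial class from an instruction
#'
#' @param emotion `"happy"` or `"sad"` (vectorised).
#' @param gaze `"left"`, `"right"` or `"straight"` (vectorised).
#' @return `"pro"`, `"anti"` or `"nogo"` per element.
#' @export
trial_class_of <- function(emotion, gaze) {
  stopifnot(all(emotion %in% c("happy", "sad")),
            all(gaze %in% c("left", "right", "straight")))
  ifelse(gaze == "straight", "nogo", ifelse(emotion == "happy", "pro", "anti"))
}

#' Expected response for an instruction
#'
#' Pro-saccade trials require a saccade toward the cued gaze direction,
#' anti-saccade trials a saccade away from it, and no-go (straight gaze)
#' trials require withholding the saccade.
#'
#' @param emotion,gaze Instruction fields (vectorised).
#' @return `"saccade_left"`, `"saccade_right"` or `"none"` per element.
#' @examples
#' expected_response("happy", "left")   # "saccade_left"
#' expected_response("sad", "left")     # "saccade_right"
#' expected_response("sad", "straight") # "none"
#' @export
expected_response <- function(emotion, gaze) {
  cls <- trial_class_of(emotion, gaze)
  out <- character(length(cls))
  out[cls == "nogo"] <- "none"
  pro <- cls == "pro"
  anti <- cls == "anti"
  out[pro] <- paste0("saccade_", gaze[pro])
  out[anti] <- ifelse(gaze[anti] == "left", "saccade_right", "saccade_left")
  out
}

#' Screen geometry and pixel/degree conversion parameters
#'
#' Describes the stimulus monitor: a 17-inch 1280 x 1024 display viewed from
#' 60 cm. Pixel coordinates are converted to degrees of visual angle with the
#' exact arctangent mapping about the screen centre (no small-angle
#' approximation). The saccade target is displayed 8.30 degrees left or right
#' of centre, and the central area used by the saccade detector has a radius
#' of 4.04 degrees.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_in Physical diagonal, inches.
#' @param distance_cm Viewing distance, cm.
#' @param target_offset_deg Horizontal target eccentricity, degrees.
#' @param center_threshold_deg Radius of the central area, degrees.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            diagonal_in = 17, distance_cm = 60,
                            target_offset_deg = 8.30,
                            center_threshold_deg = 4.04) {
  diag_px <- sqrt(width_px^2 + height_px^2)
  cm_per_px <- diagonal_in * 2.54 / diag_px
  structure(list(width_px = width_px, height_px = height_px,
                 distance_cm = distance_cm, cm_per_px = cm_per_px,
                 center_px = c(x = (width_px + 1) / 2, y = (height_px + 1) / 2),
                 target_offset_deg = target_offset_deg,
                 center_threshold_deg = center_threshold_deg),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.2f cm/px, viewed at %g cm\n",
              x$width_px, x$height_px, x$cm_per_px, x$distance_cm))
  cat(sprintf("  target offset %.2f deg, central area %.2f deg\n",
              x$target_offset_deg, x$center_threshold_deg))
  invisible(x)
}

#' Convert pixel offsets to degrees of visual angle (and back)
#'
#' Odd-symmetric exact mapping: `deg = atan(offset_cm / distance_cm)`.
#'
#' @param px Pixel coordinate (screen frame, origin at top-left for y; pass
#'   axis = "x" or "y" to pick the centre used).
#' @param geometry A [screen_geometry()].
#' @param axis `"x"` or `"y"`.
#' @return Degrees of visual angle, positive rightward (x) / upward (y).
#' @export
px_to_deg <- function(px, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  off <- px - geometry$center_px[[axis]]
  if (axis == "y") off <- -off  # screen y grows downward; degrees grow upward
  atan2(off * geometry$cm_per_px, geometry$distance_cm) * 180 / pi
}

#' @rdname px_to_deg
#' @param deg Degrees of visual angle.
#' @export
deg_to_px <- function(deg, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  off <- tan(deg * pi / 180) * geometry$distance_cm / geometry$cm_per_px
  if (axis == "y") off <- -off
  off + geometry$center_px[[axis]]
}

#' Generate a counterbalanced session of go/no-go saccade trials
#'
#' Each run holds `trials_per_run` trials split equally between pro-saccade,
#' anti-saccade and no-go classes; within pro and anti, left and right cues
#' are balanced, and within no-go, happy and sad faces are balanced (the
#' default 84-trial run gives the 28/28/28 and 14/14 splits). Trial order is
#' a seeded uniform permutation per run. Each trial carries a stage timeline
#' (Neutral 1000, Gap 500, Instruction 750, Fixation drawn from
#' {500,...,1000}, Target 200, Response 1500 ms) with onsets in ms from run
#' start; runs are laid out consecutively on one session clock separated by
#' `inter_run_gap_ms`.
#'
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param n_runs Number of runs (default 4).
#' @param trials_per_run Trials per run, divisible by 6 (default 84).
#' @param inter_run_gap_ms Silence between runs on the session clock.
#' @return A data.frame of class `session`, one row per trial, with
#'   instruction fields, stage onsets (`*_on`), `fixation_duration`,
#'   `target_side`, and `trial_start`/`trial_end` in ms.
#' @examples
#' s <- generate_session(seed = 7, n_runs = 1)
#' table(s$trial_class)
#' @export
generate_session <- function(seed, n_runs = 4, trials_per_run = 84,
                             inter_run_gap_ms = 2000) {
  stopifnot(n_runs >= 1, trials_per_run %% 6 == 0)
  set.seed(as.integer(seed))
  n6 <- trials_per_run / 6L  # copies of each of the six instructions
  base <- instructions()[rep(seq_len(6), each = n6), ]
  runs <- vector("list", n_runs)
  t0 <- 0
  for (r in seq_len(n_runs)) {
    ord <- sample.int(nrow(base))
    run <- base[ord, , drop = FALSE]
    rownames(run) <- NULL
    run$run <- r
    run$trial <- seq_len(nrow(run))
    run$fixation_duration <- sample(FIXATION_CHOICES, nrow(run), replace = TRUE)
    # target side: cue side for go trials, fair coin for no-go
    side <- run$gaze
    nogo <- side == "straight"
    side[nogo] <- sample(c("left", "right"), sum(nogo), replace = TRUE)
    run$target_side <- side
    durs <- cbind(neutral = STAGE_DURATIONS[["neutral"]],
                  gap = STAGE_DURATIONS[["gap"]],
                  instruction = STAGE_DURATIONS[["instruction"]],
                  fixation = run$fixation_duration,
                  target = STAGE_DURATIONS[["target"]],
                  response = STAGE_DURATIONS[["response"]])
    trial_len <- rowSums(durs)
    start <- t0 + c(0, cumsum(trial_len))[seq_len(nrow(run))]
    onsets <- start + t(apply(cbind(0, durs[, -6, drop = FALSE]), 1, cumsum))
    colnames(onsets) <- paste0(STAGE_NAMES, "_on")
    run <- cbind(run, as.data.frame(onsets))
    run$trial_start <- start
    run$trial_end <- start + trial_len
    t0 <- max(run$trial_end) + inter_run_gap_ms
    runs[[r]] <- run
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out <- out[, c("run", "trial", "emotion", "gaze", "trial_class",
                 "fixation_duration", "target_side",
                 paste0(STAGE_NAMES, "_on"), "trial_start", "trial_end")]
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("session", "data.frame")
  out
}

#' Write / read a session events table
#'
#' Plain TSV with a header, one row per trial.
#'
#' @param session A [generate_session()] result.
#' @param path Output file.
#' @export
write_session <- function(session, path) {
  utils::write.table(session, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("session", "data.frame")
  out
}

#' Response-eligible span of a trial
#'
#' Saccadic responses are accepted from Fixation onset (the paradigm's mean
#' response precedes the Response stage) until the end of the Response stage.
#'
#' @param trial One session row (list or single-row data.frame).
#' @return `c(start, end)` in session ms.
#' @export
response_span <- function(trial) {
  c(start = as.numeric(trial$fixation_on),
    end = as.numeric(trial$response_on) + STAGE_DURATIONS[["response"]])
}
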