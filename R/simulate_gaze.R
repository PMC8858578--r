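# Gaze-trace simulator: fixation noise, planted response saccades (correct or
# erroneous per the behaviour model), return saccades, fixational
# micro-saccades and blink-like vertical excursions, all on the session clock
# at the eye-tracker rate (120 Hz).

#' Behavioural generative model for the gaze simulator
#'
#' Defaults reproduce the study regime: an overall error probability of about
#' 5.21% in every trial class; response latencies relative to Response-stage
#' onset of -497.02 +/- 627.74 ms (correct) and -448.75 +/- 571.69 ms
#' (error), i.e. most saccades are launched during the Fixation/Target
#' stages; saccade amplitudes of 10.50 +/- 2.59 deg (correct) and
#' 9.53 +/- 2.41 deg (error); durations of 70.58 +/- 20.91 ms (correct) and
#' 56.83 +/- 15.60 ms (error). Amplitudes are truncated below at
#' `min_amplitude_deg` and durations at `min_duration_ms` so that every
#' planted response is physically detectable; latencies are truncated to the
#' trial's response-eligible span. Micro-saccades (amplitude < 2 deg) and
#' blink-like vertical excursions are planted at Poisson rates during
#' non-response periods.
#'
#' @param error_prob Named or unnamed length-3 vector of error probabilities
#'   for (pro, anti, nogo).
#' @param latency_ms Mean/SD (ms) of saccade onset minus Response onset, per
#'   outcome: list with `correct = c(mean, sd)`, `error = c(mean, sd)`.
#' @param amplitude_deg,duration_ms Mean/SD per outcome, same layout.
#' @param no_response_prob Probability that a go trial ends with no saccade
#'   at all (excluded trial).
#' @param microsaccade_rate,blink_rate Events per second during fixation.
#' @param microsaccade_amp_deg Range (uniform) of micro-saccade amplitudes.
#' @param blink_amp_deg Mean vertical excursion of a blink-like event.
#' @param noise_sd_deg SD of isotropic fixation noise, degrees.
#' @param min_amplitude_deg,min_duration_ms Truncation floors for planted
#'   responses.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(error_prob = c(pro = 0.0521, anti = 0.0521, nogo = 0.0521),
                           latency_ms = list(correct = c(-497.02, 627.74),
                                             error = c(-448.75, 571.69)),
                           amplitude_deg = list(correct = c(10.50, 2.59),
                                                error = c(9.53, 2.41)),
                           duration_ms = list(correct = c(70.58, 20.91),
                                              error = c(56.83, 15.60)),
                           no_response_prob = 0.02,
                           microsaccade_rate = 1.0,
                           blink_rate = 0.15,
                           microsaccade_amp_deg = c(0.3, 1.8),
                           blink_amp_deg = 8,
                           noise_sd_deg = 0.05,
                           min_amplitude_deg = 4.5,
                           min_duration_ms = 25) {
  stopifnot(all(error_prob >= 0), all(error_prob <= 1),
            no_response_prob >= 0, no_response_prob < 1,
            min_amplitude_deg > 0, min_duration_ms > 0)
  if (is.null(names(error_prob))) names(error_prob) <- c("pro", "anti", "nogo")
  structure(as.list(environment()), class = "behavior_model")
}

# monotone displacement profile from 0 to 1 over [0, 1]: raised cosine with
# a small linear blend so the movement is measurable from its first sample
sigmoid_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  0.85 * (1 - cos(pi * tau)) / 2 + 0.15 * tau
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
  }
  out
}

#' Simulate an eye-tracker gaze trace for a session
#'
#' Produces a 120 Hz pixel-coordinate trace covering all runs of the session
#' plus a planted ground-truth record. Correct go trials contain one saccade
#' to the instructed side (pro: cue side; anti: opposite side) landing at the
#' target eccentricity; erroneous go trials contain a saccade to the wrong
#' side; erroneous no-go trials contain a saccade to a random side; correct
#' no-go trials contain no saccade. Every planted response is followed by a
#' return saccade to centre late in the Response stage (recorded in the
#' ground truth with `role = "return"`). Micro-saccades and blink-like
#' events are planted away from response saccades.
#'
#' @param session A [generate_session()] result.
#' @param model A [behavior_model()].
#' @param geometry A [screen_geometry()].
#' @param seed Integer seed.
#' @param sfreq Tracker sampling rate, Hz.
#' @return A list with `trace` (data.frame `time_ms`, `x`, `y` in pixels,
#'   attribute `unit = "px"`) and `truth` (list with per-trial `outcomes`
#'   data.frame and an `events` data.frame of every planted saccadic event).
#' @export
simulate_gaze <- function(session, model = behavior_model(),
                          geometry = screen_geometry(), seed = 1,
                          sfreq = 120) {
  stopifnot(inherits(model, "behavior_model"))
  if (any(diff(session$trial_start) <= 0))
    stop("session timeline is not ordered")
  set.seed(as.integer(seed))
  dt <- 1000 / sfreq
  t_end <- max(session$trial_end) + 500
  tms <- seq(0, t_end, by = dt)
  x <- stats::rnorm(length(tms), 0, model$noise_sd_deg)
  y <- stats::rnorm(length(tms), 0, model$noise_sd_deg)

  outcomes <- list(); planted <- list()
  n_t <- length(tms)
  add_step <- function(coord, onset, dur, from, to) {
    # add displacement profile moving `coord` ("x"/"y") from `from` to `to`;
    # only the samples inside / after the movement are touched
    i0 <- min(n_t + 1L, findInterval(onset, tms) + 1L)
    if (i0 > n_t) return(invisible())
    idx <- i0:n_t
    prof <- sigmoid_profile((tms[idx] - onset) / dur)
    if (coord == "x") x[idx] <<- x[idx] + (to - from) * prof
    else y[idx] <<- y[idx] + (to - from) * prof
  }
  add_pulse <- function(coord, onset, dur, amp) {
    # go-and-return excursion (micro-saccade or blink)
    i0 <- min(n_t + 1L, findInterval(onset, tms) + 1L)
    i1 <- min(n_t, findInterval(onset + dur, tms))
    if (i0 > i1) return(invisible())
    idx <- i0:i1
    prof <- (1 - cos(2 * pi * (tms[idx] - onset) / dur)) / 2
    if (coord == "x") x[idx] <<- x[idx] + amp * prof
    else y[idx] <<- y[idx] + amp * prof
  }

  for (i in seq_len(nrow(session))) {
    tr <- session[i, ]
    cls <- tr$trial_class
    is_err <- stats::runif(1) < model$error_prob[[cls]]
    no_sacc <- if (cls == "nogo") !is_err else stats::runif(1) < model$no_response_prob
    span <- response_span(tr)
    outcome <- if (no_sacc) "no_saccade" else if (is_err) "error" else "correct"
    sacc <- NULL
    if (!no_sacc) {
      par <- if (is_err) "error" else "correct"
      dur <- rtrunc_norm(1, model$duration_ms[[par]][1], model$duration_ms[[par]][2],
                         lower = model$min_duration_ms)
      amp <- rtrunc_norm(1, model$amplitude_deg[[par]][1], model$amplitude_deg[[par]][2],
                         lower = model$min_amplitude_deg)
      lat <- rtrunc_norm(1, model$latency_ms[[par]][1], model$latency_ms[[par]][2],
                         lower = span[["start"]] - tr$response_on + 50,
                         upper = span[["end"]] - tr$response_on - dur - 400)
      onset <- tr$response_on + lat
      dir <- switch(cls,
        pro = if (is_err) opposite(tr$gaze) else tr$gaze,
        anti = if (is_err) tr$gaze else opposite(tr$gaze),
        nogo = sample(c("left", "right"), 1))
      sgn <- if (dir == "right") 1 else -1
      add_step("x", onset, dur, 0, sgn * amp)
      # return to centre before trial end
      ret_on <- min(onset + dur + 600, tr$trial_end - 150)
      ret_dur <- 60
      add_step("x", ret_on, ret_dur, sgn * amp, 0)
      sacc <- data.frame(run = tr$run, trial = tr$trial, role = "response",
                         onset_ms = onset, offset_ms = onset + dur,
                         amplitude_deg = amp, direction = dir)
      planted[[length(planted) + 1L]] <- rbind(sacc,
        data.frame(run = tr$run, trial = tr$trial, role = "return",
                   onset_ms = ret_on, offset_ms = ret_on + ret_dur,
                   amplitude_deg = amp, direction = opposite(dir)))
    }
    # fixational events during Neutral/Gap/Instruction (never collide with
    # the response window)
    quiet_len <- (tr$instruction_on + 500 - tr$trial_start) / 1000
    n_micro <- stats::rpois(1, model$microsaccade_rate * quiet_len)
    n_blink <- stats::rpois(1, model$blink_rate * quiet_len)
    micro_on <- sort(stats::runif(n_micro, tr$trial_start + 200,
                                  tr$instruction_on + 400))
    for (m in micro_on) {
      a <- stats::runif(1, model$microsaccade_amp_deg[1], model$microsaccade_amp_deg[2]) *
        sample(c(-1, 1), 1)
      add_pulse("x", m, stats::runif(1, 60, 120), a)
      planted[[length(planted) + 1L]] <- data.frame(
        run = tr$run, trial = tr$trial, role = "microsaccade",
        onset_ms = m, offset_ms = m + 90, amplitude_deg = abs(a),
        direction = if (a > 0) "right" else "left")
    }
    blink_on <- stats::runif(n_blink, tr$trial_start + 200, tr$instruction_on + 300)
    for (bl in blink_on) {
      add_pulse("y", bl, stats::runif(1, 200, 350), -model$blink_amp_deg)
      add_pulse("x", bl, 250, stats::runif(1, -0.5, 0.5))
      planted[[length(planted) + 1L]] <- data.frame(
        run = tr$run, trial = tr$trial, role = "blink",
        onset_ms = bl, offset_ms = bl + 300, amplitude_deg = model$blink_amp_deg,
        direction = NA_character_)
    }
    outcomes[[i]] <- data.frame(
      run = tr$run, trial = tr$trial, trial_class = cls, outcome = outcome,
      true_onset_ms = if (is.null(sacc)) NA_real_ else sacc$onset_ms,
      true_latency_ms = if (is.null(sacc)) NA_real_ else sacc$onset_ms - tr$response_on,
      true_amplitude_deg = if (is.null(sacc)) NA_real_ else sacc$amplitude_deg,
      true_duration_ms = if (is.null(sacc)) NA_real_ else sacc$offset_ms - sacc$onset_ms,
      true_direction = if (is.null(sacc)) NA_character_ else sacc$direction)
  }
  truth <- list(outcomes = do.call(rbind, outcomes),
                events = if (length(planted)) do.call(rbind, planted) else
                  data.frame())
  # degrees -> pixels (the acquisition frame)
  trace <- data.frame(time_ms = tms,
                      x = deg_to_px(x, geometry, "x"),
                      y = deg_to_px(y, geometry, "y"))
  attr(trace, "unit") <- "px"
  list(trace = trace, truth = truth)
}

opposite <- function(side) ifelse(side == "left", "right", "left")

#' Score detected saccades against planted ground truth
#'
#' Matches detected `label == "saccade"` events to planted response saccades
#' by onset proximity. Planted return saccades end at the screen centre and
#' are removed by the detector's central-area rule, so they enter neither
#' side of the match.
#'
#' @param events Detected events ([detect_events()]).
#' @param truth Ground truth from [simulate_gaze()].
#' @param tol_ms Onset matching tolerance.
#' @return List with `sensitivity`, `precision`, and the matched onset
#'   errors (ms).
#' @export
score_detection <- function(events, truth, tol_ms = 50) {
  det <- events[events$label == "saccade", , drop = FALSE]
  tru <- truth$events
  tru <- tru[tru$role == "response", , drop = FALSE]
  if (!nrow(tru)) return(list(sensitivity = NA, precision = NA, onset_err = numeric()))
  d <- outer(tru$onset_ms, det$onset_ms, function(a, b) abs(a - b))
  matched_t <- if (nrow(det)) apply(d, 1, min) <= tol_ms else rep(FALSE, nrow(tru))
  matched_d <- if (nrow(det)) apply(d, 2, min) <= tol_ms else logical()
  onset_err <- if (nrow(det)) apply(d, 1, min)[matched_t] else numeric()
  list(sensitivity = mean(matched_t),
       precision = if (nrow(det)) mean(matched_d) else NA,
       onset_err = onset_err)
}
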