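# Displacement-threshold saccade detection from the horizontal gaze
# coordinate. No velocity criterion is used anywhere: every rule is stated in
# terms of displacement, duration and endpoint position.

#' Saccade detection parameters
#'
#' Thresholds of the displacement-based detector: a saccade must (i) have a
#' horizontal amplitude of at least `min_horizontal_amplitude_deg`, (ii) last
#' at least `min_duration_ms`, (iii) have a vertical amplitude below
#' `vertical_fraction` times its horizontal amplitude (events failing this
#' are blink-like), and (iv) end outside the central area of radius
#' `min_center_distance_deg`. Sub-threshold horizontal excursions (the
#' literature bounds micro-saccades at about 2 degrees; the working threshold
#' is set higher to absorb tracker sensitivity to head micro-movements) and
#' too-short events are labelled micro-saccades.
#'
#' Event segmentation is displacement-based: a sample belongs to an event
#' while the horizontal coordinate deviates from the local fixation level (a
#' trailing running median over `baseline_window_ms`) by more than
#' `k_sd` trailing standard deviations, with an absolute floor of
#' `band_floor_deg` to keep near-noiseless traces well behaved.
#'
#' @param min_center_distance_deg Central-area radius (deg).
#' @param min_horizontal_amplitude_deg Minimum saccade amplitude (deg).
#' @param min_duration_ms Minimum saccade duration (ms).
#' @param vertical_fraction Blink rule: vertical/horizontal amplitude bound.
#' @param microsaccade_max_deg Informational literature bound (deg).
#' @param baseline_window_ms Trailing window for the fixation level (ms).
#' @param k_sd Deviation band width in trailing SDs.
#' @param band_floor_deg Absolute floor of the deviation band (deg).
#' @param stabilization_ms An ongoing event ends once the coordinate stops
#'   moving: its range over this trailing span falls within the onset band.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_center_distance_deg = 4.04,
                             min_horizontal_amplitude_deg = 4.04,
                             min_duration_ms = 15,
                             vertical_fraction = 0.80,
                             microsaccade_max_deg = 2.0,
                             baseline_window_ms = 100,
                             k_sd = 3,
                             band_floor_deg = 0.02,
                             stabilization_ms = 25) {
  stopifnot(min_center_distance_deg > 0, min_horizontal_amplitude_deg > 0,
            min_duration_ms > 0, vertical_fraction > 0, vertical_fraction < 1,
            baseline_window_ms > 0, k_sd > 0, band_floor_deg >= 0,
            stabilization_ms > 0)
  structure(as.list(environment()), class = "detection_params")
}

#' Convert a pixel gaze trace to degrees of visual angle
#'
#' Centres both coordinates on the screen centre and applies the exact
#' arctangent pixel-to-degree mapping. Non-finite samples must be flagged as
#' missing (`NA`) beforehand; any other non-finite value is an error.
#'
#' @param trace Data frame with `time_ms`, `x`, `y`. Attribute or argument
#'   `unit` may be `"px"` (converted) or `"deg"` (returned unchanged).
#' @param geometry A [screen_geometry()].
#' @param unit Unit of `x`/`y`; defaults to the trace's `unit` attribute,
#'   else `"px"`.
#' @return The trace in degrees (attribute `unit = "deg"`), rightward and
#'   upward positive.
#' @export
to_degrees <- function(trace, geometry, unit = NULL) {
  unit <- unit %||% attr(trace, "unit") %||% "px"
  stopifnot(all(c("time_ms", "x", "y") %in% names(trace)))
  if (unit == "deg") {
    attr(trace, "unit") <- "deg"
    return(trace)
  }
  stopifnot(unit == "px")
  bad <- (!is.finite(trace$x) & !is.na(trace$x)) |
    (!is.finite(trace$y) & !is.na(trace$y))
  if (any(bad)) stop("non-finite gaze coordinates that are not NA-flagged")
  trace$x <- px_to_deg(trace$x, geometry, "x")
  trace$y <- px_to_deg(trace$y, geometry, "y")
  attr(trace, "unit") <- "deg"
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trailing running median / SD over the w samples preceding each sample
# (event samples are NOT excluded; the window is over raw history, which
# keeps the definition non-recursive and independently reproducible).
trailing_stats <- function(x, w) {
  n <- length(x)
  med <- sd_ <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - w):(i - 1L)
    if (i == 1L) next
    h <- x[j]
    med[i] <- stats::median(h)
    sd_[i] <- if (length(h) >= 2) stats::sd(h) else 0
  }
  list(med = med, sd = sd_)
}

#' Detect and label gaze events in a trace
#'
#' Segments the horizontal coordinate into events with a purely
#' displacement-based state machine: an event starts at the first sample
#' deviating from the pre-event fixation level (trailing running median over
#' `baseline_window_ms`) by more than the noise band (`k_sd` trailing SDs,
#' floored at `band_floor_deg`); level and band are then frozen, and the
#' event ends when the coordinate either returns within the frozen band of
#' the pre-event level or stops moving (its range over the trailing
#' `stabilization_ms` stays within the band, as after a saccade that lands
#' on a new fixation point). Events separated by at most one sample are
#' merged. Each event is labelled by the decision rules, applied in this
#' order:
#'
#' 1. vertical amplitude >= 80% of horizontal amplitude -> `blink_like`;
#' 2. horizontal amplitude < 4.04 deg or duration < 15 ms -> `microsaccade`;
#' 3. endpoint within 4.04 deg of the screen centre -> `rejected_central`;
#' 4. otherwise -> `saccade`.
#'
#' Amplitudes are ranges (max minus min) of each coordinate over the event
#' span extended to the last pre-onset sample; duration is offset time minus
#' onset time; the endpoint is the last event sample. Traces are split at
#' gaps (missing samples or timestamp jumps beyond 1.5 sampling intervals)
#' and events never span a gap. Detection only uses time differences, so it
#' is invariant to shifting all timestamps by a constant.
#'
#' @param trace Gaze trace in degrees (see [to_degrees()]).
#' @param params A [detection_params()].
#' @return A data.frame of events ordered by onset: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `h_amplitude_deg`, `v_amplitude_deg`, `direction`
#'   (`"left"`/`"right"`), `end_distance_deg`, `label`.
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if ((attr(trace, "unit") %||% "deg") != "deg")
    stop("trace must be in degrees; call to_degrees() first")
  empty <- data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      duration_ms = numeric(), h_amplitude_deg = numeric(),
                      v_amplitude_deg = numeric(), direction = character(),
                      end_distance_deg = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(trace)
  if (n == 0) return(empty)
  if (is.unsorted(trace$time_ms)) stop("trace must be time-ordered")
  t <- trace$time_ms; x <- trace$x; y <- trace$y
  dt <- stats::median(diff(t))
  if (!is.finite(dt) || dt <= 0) return(empty)
  # block boundaries: missing samples or time gaps
  ok <- is.finite(x) & is.finite(y)
  brk <- c(TRUE, diff(t) > 1.5 * dt) | !ok
  block <- cumsum(brk)
  block[!ok] <- NA
  out <- list()
  for (b in unique(block[!is.na(block)])) {
    idx <- which(!is.na(block) & block == b)
    if (length(idx) < 2) next
    ev <- detect_events_block(t[idx], x[idx], y[idx], dt, params)
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out[order(out$onset_ms), , drop = FALSE] |> `rownames<-`(NULL)
}

detect_events_block <- function(t, x, y, dt, params) {
  w <- max(3L, round(params$baseline_window_ms / dt))
  s_stab <- max(2L, round(params$stabilization_ms / dt))
  ts <- trailing_stats(x, w)
  band <- pmax(params$k_sd * ts$sd, params$band_floor_deg)
  n <- length(x)
  on <- integer(); off <- integer()
  i <- 2L
  while (i <= n) {
    if (!is.na(ts$med[i]) && abs(x[i] - ts$med[i]) > band[i]) {
      l0 <- ts$med[i]; b0 <- band[i]
      j <- i
      while (j < n) {
        nxt <- j + 1L
        if (abs(x[nxt] - l0) <= b0) break  # back at the pre-event level
        j <- nxt
        if (j - i + 1L >= s_stab &&
            diff(range(x[(j - s_stab + 1L):j])) <= b0) break  # stopped moving
      }
      on <- c(on, i); off <- c(off, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(on)) return(data.frame())
  # merge events separated by at most one sample
  if (length(on) > 1) {
    keep_on <- on[1]; m_on <- c(); m_off <- c()
    cur_off <- off[1]
    for (k in seq_along(on)[-1]) {
      if (on[k] - cur_off <= 2L) {  # gap of <= 1 sample between runs
        cur_off <- off[k]
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, cur_off)
        keep_on <- on[k]; cur_off <- off[k]
      }
    }
    on <- c(m_on, keep_on); off <- c(m_off, cur_off)
  }
  label_events(t, x, y, on, off, params)
}

# Shared labeller: applies the amplitude/duration/blink/central-area rules to
# segmented [on, off] sample runs.
label_events <- function(t, x, y, on, off, params) {
  res <- lapply(seq_along(on), function(k) {
    i0 <- max(1L, on[k] - 1L)  # include last pre-onset sample in amplitudes
    span <- i0:off[k]
    h_amp <- max(x[span]) - min(x[span])
    v_amp <- max(y[span]) - min(y[span])
    dur <- t[off[k]] - t[on[k]]
    endd <- sqrt(x[off[k]]^2 + y[off[k]]^2)
    dir <- if (x[off[k]] >= x[i0]) "right" else "left"
    label <-
      if (v_amp >= params$vertical_fraction * h_amp) "blink_like"
      else if (h_amp < params$min_horizontal_amplitude_deg ||
               dur < params$min_duration_ms) "microsaccade"
      else if (endd < params$min_center_distance_deg) "rejected_central"
      else "saccade"
    data.frame(onset_ms = t[on[k]], offset_ms = t[off[k]], duration_ms = dur,
               h_amplitude_deg = h_amp, v_amplitude_deg = v_amp,
               direction = dir, end_distance_deg = endd, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' First saccade within a trial's response-eligible span
#'
#' @param events Event table from [detect_events()], sorted by onset.
#' @param trial One session row; the span runs from Fixation onset to the
#'   end of the Response stage (see [response_span()]).
#' @return The earliest `label == "saccade"` event row whose onset falls in
#'   the span, or `NULL` if there is none.
#' @export
first_saccade_in_trial <- function(events, trial) {
  span <- response_span(trial)
  hit <- events$label == "saccade" &
    events$onset_ms >= span[["start"]] & events$onset_ms <= span[["end"]]
  if (!any(hit)) return(NULL)
  events[which(hit)[1], , drop = FALSE]
}

#' Write a gaze event table as TSV
#' @param events Event table from [detect_events()].
#' @param path Output file.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
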