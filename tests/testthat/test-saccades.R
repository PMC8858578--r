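test_that("textbook events receive the textbook labels", {
  p <- detection_params()
  # 5 deg rightward displacement over 30 ms, flat vertical -> saccade right
  tr <- add_ramp(make_trace(seed = 2), 1000, 30, 5)
  ev <- detect_events(tr, p)
  sac <- ev[ev$label == "saccade", ]
  expect_equal(nrow(sac), 1)
  expect_equal(sac$direction, "right")
  expect_gt(sac$h_amplitude_deg, 4.04)
  # 1.5 deg displacement -> micro-saccade
  ev <- detect_events(add_ramp(make_trace(seed = 3), 1000, 30, 1.5), p)
  expect_true(all(ev$label != "saccade"))
  expect_true(any(ev$label == "microsaccade"))
  # vertical amplitude at 90% of horizontal -> blink-like
  tr <- add_ramp(add_ramp(make_trace(seed = 4), 1000, 30, 5, "x"),
                 1000, 30, 4.5, "y")
  ev <- detect_events(tr, p)
  expect_true("blink_like" %in% ev$label)
  expect_false("saccade" %in% ev$label)
  # 5 deg spike lasting < 15 ms -> micro-saccade by the duration rule
  tr <- make_trace(seed = 5)
  i <- which(tr$time_ms >= 1000)[1]
  tr$x[i] <- tr$x[i] + 5  # one-sample excursion
  ev <- detect_events(tr, p)
  expect_true(all(ev$label != "saccade"))
  # amplitude above threshold but endpoint inside the central area
  tr <- add_pulse_tr(make_trace(seed = 6), 1000, 60, 6)
  ev <- detect_events(tr, p)
  expect_true("rejected_central" %in% ev$label)
  expect_false("saccade" %in% ev$label)
})

test_that("detector agrees exactly with the brute-force reference", {
  p <- detection_params()
  n_mismatch <- 0
  for (seed in 1:120) {
    tr <- random_trace(seed)
    got <- detect_events(tr, p)
    want <- oracle_detect(tr$time_ms, tr$x, tr$y, p)
    if (is.null(want)) {
      if (nrow(got) != 0) n_mismatch <- n_mismatch + 1
    } else if (!isTRUE(all.equal(got, want, check.attributes = FALSE))) {
      n_mismatch <- n_mismatch + 1
    }
  }
  expect_equal(n_mismatch, 0)
})

test_that("no event below the amplitude threshold is ever a saccade", {
  p <- detection_params()
  for (seed in 200:240) {
    ev <- detect_events(random_trace(seed), p)
    sac <- ev[ev$label == "saccade", ]
    expect_true(all(sac$h_amplitude_deg >= p$min_horizontal_amplitude_deg))
    expect_true(all(sac$duration_ms >= p$min_duration_ms))
    expect_true(all(sac$v_amplitude_deg < p$vertical_fraction * sac$h_amplitude_deg))
    expect_true(all(sac$end_distance_deg >= p$min_center_distance_deg))
  }
})

test_that("detection is invariant to a constant timestamp shift", {
  tr <- random_trace(7)
  ev1 <- detect_events(tr)
  tr$time_ms <- tr$time_ms + 12345
  ev2 <- detect_events(tr)
  expect_equal(ev2$onset_ms - 12345, ev1$onset_ms)
  expect_equal(ev2$label, ev1$label)
})

test_that("traces with gaps are split and empty traces give empty tables", {
  expect_equal(nrow(detect_events(make_trace(0))), 0)
  # a saccade interrupted by missing samples must not span the gap
  tr <- add_ramp(make_trace(seed = 8), 1000, 30, 6)
  mid <- which(tr$time_ms > 1005 & tr$time_ms < 1025)
  tr$x[mid] <- NA
  ev <- detect_events(tr)
  expect_true(all(ev$onset_ms > max(tr$time_ms[mid]) |
                  ev$offset_ms < min(tr$time_ms[mid])))
})

test_that("first_saccade_in_trial honours order, label and span", {
  s <- mini_session(4)
  tr <- s[2, ]
  span <- response_span(tr)
  ev <- data.frame(onset_ms = c(span[1] - 50, span[1] + 100, span[1] + 300,
                                span[2] + 200),
                   offset_ms = c(span[1] - 20, span[1] + 140, span[1] + 340,
                                 span[2] + 240),
                   duration_ms = 40, h_amplitude_deg = 8, v_amplitude_deg = 0.2,
                   direction = "left", end_distance_deg = 8,
                   label = c("saccade", "microsaccade", "saccade", "saccade"))
  got <- first_saccade_in_trial(ev, tr)
  expect_equal(got$onset_ms, span[[1]] + 300)  # earliest eligible saccade
  # only micro-saccades in span -> none
  ev2 <- ev[2, ]
  expect_null(first_saccade_in_trial(ev2, tr))
  # saccade outside the span -> none
  expect_null(first_saccade_in_trial(ev[c(1, 4), ], tr))
})

test_that("to_degrees validates input and converts both axes", {
  g <- screen_geometry()
  tr <- data.frame(time_ms = 0:2 * 8.33,
                   x = deg_to_px(c(0, 4, -4), g, "x"),
                   y = deg_to_px(c(0, 1, -1), g, "y"))
  attr(tr, "unit") <- "px"
  d <- to_degrees(tr, g)
  expect_equal(d$x, c(0, 4, -4), tolerance = 1e-10)
  expect_equal(d$y, c(0, 1, -1), tolerance = 1e-10)
  tr$x[2] <- Inf
  expect_error(to_degrees(tr, g), "non-finite")
  tr$x[2] <- NA  # flagged missing is allowed
  expect_silent(to_degrees(tr, g))
})
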