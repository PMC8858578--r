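# Independent reference implementations used as oracles. They share only
# the published rule definitions with the package, not its code paths.

# Brute-force saccade labeller: literal sample-by-sample loops applying the
# documented segmentation rules (trailing median/SD band for the onset,
# frozen level/band plus return-or-stabilise for the offset), greedy merge,
# then literal application of the four labelling rules. Assumes a gap-free,
# finite, uniformly sampled trace in degrees.
oracle_detect <- function(t, x, y, params = detection_params()) {
  n <- length(x)
  dt <- stats::median(diff(t))
  w <- max(3L, round(params$baseline_window_ms / dt))
  s_stab <- max(2L, round(params$stabilization_ms / dt))
  level <- rep(NA_real_, n); band <- rep(NA_real_, n)
  for (i in 2:n) {
    h <- x[max(1L, i - w):(i - 1L)]
    level[i] <- stats::median(h)
    s <- if (length(h) >= 2) stats::sd(h) else 0
    band[i] <- max(params$k_sd * s, params$band_floor_deg)
  }
  pairs <- list()
  i <- 2L
  while (i <= n) {
    if (is.na(level[i]) || abs(x[i] - level[i]) <= band[i]) {
      i <- i + 1L
      next
    }
    l0 <- level[i]; b0 <- band[i]
    j <- i
    repeat {
      if (j == n) break
      if (abs(x[j + 1L] - l0) <= b0) break          # returned to baseline
      j <- j + 1L
      if (j - i + 1L >= s_stab) {                   # movement has stopped?
        tail_x <- x[(j - s_stab + 1L):j]
        if (max(tail_x) - min(tail_x) <= b0) break
      }
    }
    pairs[[length(pairs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  if (!length(pairs)) return(NULL)
  # greedy merge of runs separated by at most one sample
  merged <- list(pairs[[1]])
  for (p in pairs[-1]) {
    last <- merged[[length(merged)]]
    if (p[1] - last[2] <= 2L) merged[[length(merged)]] <- c(last[1], p[2])
    else merged[[length(merged) + 1L]] <- p
  }
  rows <- lapply(merged, function(p) {
    i0 <- max(1L, p[1] - 1L)
    span <- i0:p[2]
    h_amp <- max(x[span]) - min(x[span])
    v_amp <- max(y[span]) - min(y[span])
    dur <- t[p[2]] - t[p[1]]
    endd <- sqrt(x[p[2]]^2 + y[p[2]]^2)
    label <- if (v_amp >= params$vertical_fraction * h_amp) "blink_like"
      else if (h_amp < params$min_horizontal_amplitude_deg ||
               dur < params$min_duration_ms) "microsaccade"
      else if (endd < params$min_center_distance_deg) "rejected_central"
      else "saccade"
    data.frame(onset_ms = t[p[1]], offset_ms = t[p[2]], duration_ms = dur,
               h_amplitude_deg = h_amp, v_amplitude_deg = v_amp,
               direction = if (x[p[2]] >= x[i0]) "right" else "left",
               end_distance_deg = endd, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (valid for small n without ties/zeros).
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# JZS paired BF via the alternative route: marginalise the noncentral-t
# likelihood over the Cauchy effect prior.
oracle_jzs_bf10 <- function(t_stat, n, r = sqrt(2) / 2) {
  nu <- n - 1
  f <- function(delta)
    stats::dt(t_stat, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
  num <- suppressWarnings(stats::integrate(f, -Inf, Inf, rel.tol = 1e-8)$value)
  num / stats::dt(t_stat, nu)
}

# random synthetic gaze trace with planted event mix, for detector
# equivalence testing; returns a gap-free degree-unit trace
random_trace <- function(seed, dur_ms = 2500, sfreq = 120) {
  set.seed(seed)
  dt <- 1000 / sfreq
  t <- seq(0, dur_ms, by = dt)
  noise <- stats::runif(1, 0.01, 0.12)
  x <- stats::rnorm(length(t), 0, noise)
  y <- stats::rnorm(length(t), 0, noise)
  lvl <- 0
  n_ev <- sample(0:4, 1)
  if (n_ev > 0) for (on in sort(stats::runif(n_ev, 200, dur_ms - 400))) {
    kind <- sample(c("saccade", "small", "spike", "blink", "return"), 1)
    tau <- (t - on)
    if (kind == "saccade") {
      amp <- stats::runif(1, 4.2, 12) * sample(c(-1, 1), 1)
      dur <- stats::runif(1, 20, 80)
      x <- x + amp * errtheta:::sigmoid_profile(tau / dur)
      lvl <- lvl + amp
    } else if (kind == "small") {
      amp <- stats::runif(1, 0.5, 3) * sample(c(-1, 1), 1)
      x <- x + amp * errtheta:::sigmoid_profile(tau / stats::runif(1, 15, 60))
      lvl <- lvl + amp
    } else if (kind == "spike") {
      pr <- ifelse(tau > 0 & tau < 10, 1, 0)
      x <- x + stats::runif(1, 4.2, 6) * pr * sample(c(-1, 1), 1)
    } else if (kind == "blink") {
      dur <- stats::runif(1, 150, 300)
      pr <- ifelse(tau > 0 & tau < dur,
                   (1 - cos(2 * pi * pmin(pmax(tau / dur, 0), 1))) / 2, 0)
      y <- y - stats::runif(1, 5, 9) * pr
      x <- x + stats::runif(1, -0.6, 0.6) * pr
    } else {
      x <- x - lvl * errtheta:::sigmoid_profile(tau / 50)
      lvl <- 0
    }
  }
  out <- data.frame(time_ms = t, x = x, y = y)
  attr(out, "unit") <- "deg"
  out
}
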