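# Multichannel EEG simulator: 1/f background on every channel, a midfrontal
# theta carrier whose amplitude is stepped around each planted saccade onset
# to realise the configured condition-dependent power cells, EOG channels
# carrying saccade/blink waveforms, and a distance-decaying ocular leakage
# into the scalp channels.

#' Configuration of planted EEG effects
#'
#' Theta power is planted as dB relative to the trial's Gap baseline in four
#' cells: pre/post response x correct/error. Defaults are the study-scale
#' values (pre-correct 1.58, pre-error 1.26, post-correct 1.35, post-error
#' 2.31 dB): theta is higher before correct than before erroneous responses
#' and higher after errors than after correct responses. The theta carrier
#' (default 6 Hz) has a baseline amplitude `theta_amplitude_uv` at FCz with
#' a Gaussian spatial profile of width `theta_spread_cm`, and the 1/f
#' background is scaled so that its 4-8 Hz band power at FCz is
#' `bg_band_ratio` of the baseline theta band power. Each planted pre/post
#' segment's theta power is additionally jittered by
#' `trial_jitter_db` (SD, dB) to model trial-to-trial variability.
#'
#' @param theta_db Named vector with `pre_correct`, `pre_error`,
#'   `post_correct`, `post_error` (dB re Gap baseline).
#' @param theta_freq_hz Theta carrier frequency, within 4-8 Hz.
#' @param theta_amplitude_uv Baseline carrier amplitude at FCz, microvolt.
#' @param theta_spread_cm Gaussian width of the theta topography.
#' @param bg_exponent Spectral exponent of the 1/f background.
#' @param bg_band_ratio Background-to-theta band power ratio at FCz.
#' @param trial_jitter_db Per-segment theta power jitter SD, dB.
#' @param ocular_gain Leakage of the EOG signals into the scalp channels at
#'   the frontal pole (decays with distance; 0 disables leakage).
#' @param ocular_decay_cm Exponential decay length of the leakage.
#' @param ramp_ms Raised-cosine amplitude transition length at segment
#'   boundaries.
#' @return An object of class `eeg_effect_config`.
#' @export
eeg_effect_config <- function(theta_db = c(pre_correct = 1.58, pre_error = 1.26,
                                           post_correct = 1.35, post_error = 2.31),
                              theta_freq_hz = 6,
                              theta_amplitude_uv = 20,
                              theta_spread_cm = 5,
                              bg_exponent = 1,
                              bg_band_ratio = 0.01,
                              trial_jitter_db = 0.25,
                              ocular_gain = 0.02,
                              ocular_decay_cm = 6,
                              ramp_ms = 40) {
  stopifnot(theta_freq_hz >= 4, theta_freq_hz <= 8,
            all(c("pre_correct", "pre_error", "post_correct", "post_error")
                %in% names(theta_db)),
            bg_band_ratio >= 0, theta_amplitude_uv > 0)
  structure(as.list(environment()), class = "eeg_effect_config")
}

# 1/f^alpha noise via spectral shaping; returns len x ncol matrix with
# per-column SD ~= sd. Flat below f_knee to keep power finite. Generated at
# the next 2-3-5-smooth length (FFT speed) and truncated.
pink_noise <- function(len, ncol, fs, alpha = 1, sd = 1, f_knee = 0.5) {
  len_out <- len
  len <- stats::nextn(len, c(2, 3, 5))
  f <- seq(0, fs / 2, length.out = floor(len / 2) + 1)
  shape <- 1 / pmax(f, f_knee)^(alpha / 2)
  shape[1] <- 0  # no DC
  nf <- length(shape)
  re <- matrix(stats::rnorm(nf * ncol), nf)
  im <- matrix(stats::rnorm(nf * ncol), nf)
  spec <- (re + 1i * im) * shape
  spec[1, ] <- 0
  if (len %% 2 == 0) spec[nf, ] <- Re(spec[nf, ])
  full <- rbind(spec, Conj(spec[rev(seq(2, nf - 1 + len %% 2)), , drop = FALSE]))
  x <- Re(stats::mvfft(full, inverse = TRUE)) / nrow(full)
  x <- x[seq_len(len_out), , drop = FALSE]
  sc <- sd / sqrt(mean(apply(x, 2, stats::var)))
  x * sc
}

# fraction of unit-variance pink noise that the package Welch estimator
# reports as band power. This is measured against the estimator itself
# (Monte Carlo under a preserved, fixed internal seed) rather than computed
# from the generation grid, because with 250 ms windows a 1/f spectrum
# leaks considerable low-frequency power into the 4-8 Hz bins and the
# planted-power calibration must match what the estimator sees.
pink_band_fraction <- function(len, fs, alpha = 1, band = c(4, 8),
                               f_knee = 0.5, n_mc = 400) {
  key <- paste("bf", len, fs, alpha, band[1], band[2], f_knee, sep = "_")
  hit <- .capture_cache[[key]]
  if (!is.null(hit)) return(hit)
  seed_keep <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(seed_keep))
    assign(".Random.seed", seed_keep, globalenv()), add = TRUE)
  set.seed(795031L)
  x <- pink_noise(len, n_mc, fs, alpha, sd = 1, f_knee = f_knee)
  .capture_cache[[key]] <- mean(band_power_welch(x, fs, band))
  .capture_cache[[key]]
}

# mean fraction of a unit-amplitude sinusoid's power (A^2/2) captured in
# `band` by the package Welch estimator, averaged over carrier phase
# (deterministic; memoised, it is called in simulation hot loops)
.capture_cache <- new.env(parent = emptyenv())

band_capture <- function(f0, fs, seg_len, band = c(4, 8), n_phase = 16) {
  key <- paste(f0, fs, seg_len, band[1], band[2], n_phase, sep = "_")
  hit <- .capture_cache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- seq_len(seg_len) / fs
  ph <- seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)]
  caps <- vapply(ph, function(p) {
    bp <- band_power_welch(matrix(sin(2 * pi * f0 * tt + p), ncol = 1),
                           fs = fs, band = band)
    bp / 0.5
  }, numeric(1))
  .capture_cache[[key]] <- mean(caps)
  .capture_cache[[key]]
}

# amplitude realising a planted dB (re baseline) given the baseline carrier
# amplitude a0, band-capture factors and in-band background power b
planted_amplitude <- function(db, a0, kappa_seg, kappa_gap, b) {
  target <- 10^(db / 10) * (kappa_gap * a0^2 / 2 + b)
  sqrt(pmax(2 * (target - b) / kappa_seg, 0))
}

#' Simulate a multichannel EEG recording for a session
#'
#' Generates a 1000 Hz recording whose channels are the montage's 64 (or 16
#' in the `"small"` layout) scalp electrodes plus 4 EOG channels. FCz (and
#' neighbours, via the Gaussian theta topography) carries a continuous theta
#' carrier; within [-500, 0) and [0, +500) ms around each planted response
#' saccade the carrier amplitude is stepped to realise the configured cell
#' dB relative to the trial's Gap-baseline theta level. EOG channels carry
#' horizontal saccade steps and vertical blink transients derived from the
#' gaze ground truth, and every scalp channel receives those ocular signals
#' scaled by a gain decaying with distance from the frontal pole.
#'
#' @param session A [generate_session()] result.
#' @param truth Ground truth from [simulate_gaze()].
#' @param cfg An [eeg_effect_config()].
#' @param seed Integer seed.
#' @param sfreq Sampling rate, Hz.
#' @param montage A [standard_montage()] table (must contain FCz and Pz).
#' @return An `eeg_recording`: list with `data` (samples x channels matrix,
#'   microvolt), `sfreq`, `montage`, `ch_names`, `ch_types`, `t0_ms`.
#' @export
simulate_eeg <- function(session, truth, cfg = eeg_effect_config(), seed = 1,
                         sfreq = 1000, montage = standard_montage("full")) {
  stopifnot(inherits(cfg, "eeg_effect_config"))
  if (!all(c("FCz", "Pz") %in% montage$channel))
    stop("montage must include FCz and Pz")
  set.seed(as.integer(seed))
  t_end <- max(session$trial_end) + 500
  n <- floor(t_end / 1000 * sfreq) + 1
  tms <- (seq_len(n) - 1) / sfreq * 1000
  ch <- montage$channel
  is_eeg <- montage$type == "eeg"

  # background + theta band calibration
  a0 <- cfg$theta_amplitude_uv
  frac <- pink_band_fraction(round(sfreq / 2), sfreq, cfg$bg_exponent)
  kappa <- band_capture(cfg$theta_freq_hz, sfreq, round(sfreq / 2))
  b_band <- cfg$bg_band_ratio * kappa * a0^2 / 2
  bg_sd <- sqrt(b_band / frac)
  data <- pink_noise(n, length(ch), sfreq, cfg$bg_exponent, sd = bg_sd)

  # theta amplitude envelope on the session clock
  env <- rep(a0, n)
  oc <- truth$outcomes
  resp <- oc[!is.na(oc$true_onset_ms), , drop = FALSE]
  cells <- cfg$theta_db
  set_seg <- function(t0, t1, amp) {
    i0 <- max(1L, ceiling(t0 / 1000 * sfreq) + 1L)
    i1 <- min(n, ceiling(t1 / 1000 * sfreq))
    if (i0 <= i1) env[i0:i1] <<- amp
  }
  for (k in seq_len(nrow(resp))) {
    on <- resp$true_onset_ms[k]
    outc <- resp$outcome[k]
    d_pre <- cells[[paste0("pre_", substr(outc, 1, 7))]] +
      stats::rnorm(1, 0, cfg$trial_jitter_db)
    d_post <- cells[[paste0("post_", substr(outc, 1, 7))]] +
      stats::rnorm(1, 0, cfg$trial_jitter_db)
    set_seg(on - 500, on, planted_amplitude(d_pre, a0, kappa, kappa, b_band))
    set_seg(on, on + 500, planted_amplitude(d_post, a0, kappa, kappa, b_band))
  }
  # raised-cosine smoothing of envelope steps
  rl <- max(2, round(cfg$ramp_ms / 1000 * sfreq))
  ker <- (1 - cos(2 * pi * seq_len(rl) / (rl + 1))) / 2
  ker <- ker / sum(ker)
  env <- stats::filter(env, ker, sides = 2)
  env[is.na(env)] <- a0
  theta <- as.numeric(env) * sin(2 * pi * cfg$theta_freq_hz * tms / 1000 +
                                   stats::runif(1, 0, 2 * pi))

  # topographies
  i_fcz <- match("FCz", ch)
  d_fcz <- sqrt((montage$x_cm - montage$x_cm[i_fcz])^2 +
                (montage$y_cm - montage$y_cm[i_fcz])^2 +
                (montage$z_cm - montage$z_cm[i_fcz])^2)
  g_theta <- exp(-d_fcz^2 / (2 * cfg$theta_spread_cm^2))
  g_theta[!is_eeg] <- 0
  data <- data + outer(theta, g_theta)

  # ocular signals from the gaze ground truth
  h <- v <- numeric(n)
  ev <- truth$events
  if (is.data.frame(ev) && nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      on_k <- ev$onset_ms[k]; off_k <- ev$offset_ms[k]
      sgn <- if (identical(ev$direction[k], "left")) -1 else 1
      i0 <- max(1L, floor(on_k / 1000 * sfreq) + 1L)
      if (ev$role[k] %in% c("response", "return")) {
        idx <- i0:n  # permanent displacement until the paired return
        prof <- sigmoid_profile((tms[idx] - on_k) / (off_k - on_k))
        h[idx] <- h[idx] + sgn * ev$amplitude_deg[k] * prof *
          (if (ev$role[k] == "return") -1 else 1)
      } else {
        i1 <- min(n, ceiling(off_k / 1000 * sfreq))
        if (i0 > i1) next
        idx <- i0:i1
        prof <- (1 - cos(2 * pi * pmin(pmax((tms[idx] - on_k) /
                                              (off_k - on_k), 0), 1))) / 2
        if (ev$role[k] == "microsaccade")
          h[idx] <- h[idx] + sgn * ev$amplitude_deg[k] * prof
        else v[idx] <- v[idx] + ev$amplitude_deg[k] * prof
      }
    }
  }
  eog_noise <- matrix(stats::rnorm(n * 4, 0, 2), n)
  heog <- h * 8   # ~8 uV per degree
  veog <- v * 15
  eog <- cbind(HEOG_L = -heog, HEOG_R = heog,
               VEOG_U = veog, VEOG_D = -0.6 * veog) + eog_noise
  data[, !is_eeg] <- eog[, match(ch[!is_eeg], colnames(eog))]

  if (cfg$ocular_gain > 0) {
    i_fp <- match("Fpz", ch)
    if (is.na(i_fp)) i_fp <- which(is_eeg)[1]
    d_fp <- sqrt((montage$x_cm - montage$x_cm[i_fp])^2 +
                 (montage$y_cm - montage$y_cm[i_fp])^2 +
                 (montage$z_cm - montage$z_cm[i_fp])^2)
    g_oc <- cfg$ocular_gain * exp(-d_fp / cfg$ocular_decay_cm)
    g_oc[!is_eeg] <- 0
    data <- data + outer(heog * 0.7 + veog, g_oc)
  }

  colnames(data) <- ch
  structure(list(data = data, sfreq = sfreq, montage = montage,
                 ch_names = ch, ch_types = montage$type, t0_ms = 0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels (%d EEG), %.1f s at %g Hz\n",
              length(x$ch_names), sum(x$ch_types == "eeg"),
              nrow(x$data) / x$sfreq, x$sfreq))
  invisible(x)
}
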