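# EEG preprocessing and response-locked analysis: zero-phase FIR band-pass,
# downsampling, automated bad-channel flagging, average reference,
# spherical-spline interpolation, saccade-locked epoching, ERP window means,
# and Gap-baseline-normalised theta band power.

#' Preprocessing configuration
#'
#' @param l_freq,h_freq Band edges, Hz (default 0.05-45).
#' @param resample_to Target rate after filtering, Hz; must divide the
#'   recording rate.
#' @param n_taps FIR length in samples at 1000 Hz (odd; scaled with the
#'   actual rate). A windowed-sinc (Hamming) kernel of this length has a
#'   transition band of roughly `3.3 / (n_taps / fs)` Hz.
#' @param bad_z Robust z-score threshold for automated bad-channel flagging.
#' @param reject_ptp_uv Peak-to-peak epoch rejection threshold, microvolt.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(l_freq = 0.05, h_freq = 45, resample_to = 500,
                           n_taps = 3301, bad_z = 5, reject_ptp_uv = 150) {
  stopifnot(0 < l_freq, l_freq < h_freq, h_freq < resample_to / 2,
            n_taps %% 2 == 1)
  structure(as.list(environment()), class = "preproc_config")
}

#' Design the zero-phase band-pass FIR kernel
#'
#' Windowed-sinc (Hamming) linear-phase type-I kernel via [signal::fir1].
#' Applied by symmetric convolution with delay compensation the kernel is
#' exactly zero-phase.
#'
#' @param cfg A [preproc_config()].
#' @param fs Sampling rate, Hz.
#' @return Numeric kernel of odd length.
#' @export
design_fir <- function(cfg, fs) {
  n_taps <- round(cfg$n_taps * fs / 1000)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  signal::fir1(n_taps - 1, c(cfg$l_freq, cfg$h_freq) * 2 / fs, type = "pass")
}

# zero-phase filtering: FFT convolution with the symmetric kernel, delay
# compensated; edges are reflection-padded to limit transients
filter_zerophase <- function(x, h) {
  apply_one <- function(v) {
    m <- (length(h) - 1) / 2
    pad <- min(m, length(v) - 1)
    vp <- c(rev(v[2:(pad + 1)]), v, rev(v[(length(v) - pad):(length(v) - 1)]))
    nfft <- stats::nextn(length(vp) + length(h) - 1, 2)
    y <- Re(stats::fft(stats::fft(c(vp, rep(0, nfft - length(vp)))) *
                       stats::fft(c(h, rep(0, nfft - length(h)))),
                       inverse = TRUE)) / nfft
    y[(pad + m + 1):(pad + m + length(v))]
  }
  if (is.matrix(x)) apply(x, 2, apply_one) else apply_one(x)
}

#' Flag bad channels by robust statistics
#'
#' A scalp channel is flagged when the robust z-score (median/MAD across
#' channels) of its log variance or of its log high-frequency (20 Hz to the
#' upper band edge) power exceeds `bad_z`. This replaces visual inspection
#' with a reproducible criterion.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preproc_config()].
#' @return Character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(rec, cfg = preproc_config()) {
  eeg <- rec$ch_types == "eeg"
  x <- rec$data[, eeg, drop = FALSE]
  v <- log(apply(x, 2, stats::var))
  hf <- log(vapply(seq_len(ncol(x)), function(j)
    band_power_welch(x[, j, drop = FALSE], rec$sfreq,
                     band = c(20, cfg$h_freq), window_sec = 0.5),
    numeric(1)))
  rz <- function(u) (u - stats::median(u)) / max(stats::mad(u), 1e-12)
  bad <- abs(rz(v)) > cfg$bad_z | abs(rz(hf)) > cfg$bad_z
  colnames(x)[bad]
}

#' Preprocess a continuous recording
#'
#' Zero-phase FIR band-pass (0.05-45 Hz), decimation to 500 Hz (safe: the
#' upper band edge is far below the new Nyquist), automated bad-channel
#' flagging, average reference over the good scalp channels (EOG excluded),
#' an optional artifact-reduction hook (e.g. a decomposition-based ocular
#' cleanup supplied by the caller), then spherical-spline interpolation of
#' the flagged channels. Fails if FCz or Pz is flagged.
#'
#' @param rec An `eeg_recording` from [simulate_eeg()] or [read_brainvision()].
#' @param cfg A [preproc_config()].
#' @param artifact_fn Optional hook `function(data, rec)` returning a cleaned
#'   data matrix, run between referencing and interpolation.
#' @return A cleaned `eeg_recording` with attributes `bad_channels` and
#'   `sfreq` updated.
#' @export
preprocess <- function(rec, cfg = preproc_config(), artifact_fn = NULL) {
  stopifnot(inherits(cfg, "preproc_config"))
  if (!all(c("FCz", "Pz") %in% rec$ch_names)) stop("montage lacks FCz or Pz")
  h <- design_fir(cfg, rec$sfreq)
  data <- filter_zerophase(rec$data, h)
  dec <- rec$sfreq / cfg$resample_to
  if (dec != round(dec)) stop("resample_to must divide the recording rate")
  if (dec > 1) data <- data[seq(1, nrow(data), by = dec), , drop = FALSE]
  out <- rec
  out$data <- data
  out$sfreq <- cfg$resample_to
  bad <- detect_bad_channels(out, cfg)
  if (any(c("FCz", "Pz") %in% bad))
    stop("channel of interest (FCz/Pz) flagged as bad; aborting")
  eeg <- out$ch_types == "eeg"
  good <- eeg & !(out$ch_names %in% bad)
  ref <- rowMeans(out$data[, good, drop = FALSE])
  out$data[, eeg] <- out$data[, eeg, drop = FALSE] - ref
  if (!is.null(artifact_fn)) out$data <- artifact_fn(out$data, out)
  if (length(bad))
    out$data[, bad] <- interpolate_channels(out$data, out$montage,
                                            out$ch_names, bad)
  out$bad_channels <- bad
  out
}

# ---------------------------------------------------------------------------
# Spherical-spline interpolation (Perrin-style, stiffness m = 4).

spline_g <- function(cosang, m = 4, nterms = 20) {
  # g(x) = 1/(4*pi) * sum_n (2n+1) / (n (n+1))^m * P_n(x)
  x <- cosang
  p_prev <- rep(1, length(x)); p <- x
  acc <- (2 * 1 + 1) / (1 * 2)^m * p
  for (n in 2:nterms) {
    p_next <- ((2 * n - 1) * x * p - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p; p <- p_next
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of flagged channels
#'
#' @param data Samples x channels matrix.
#' @param montage A [standard_montage()] table.
#' @param ch_names Column order of `data`.
#' @param bad Channels to reconstruct from the remaining good EEG channels.
#' @param lambda Ridge regularisation of the spline system.
#' @return Matrix of reconstructed columns (samples x length(bad)).
#' @export
interpolate_channels <- function(data, montage, ch_names, bad, lambda = 1e-5) {
  eegn <- montage$channel[montage$type == "eeg"]
  goodn <- setdiff(eegn, bad)
  pos <- as.matrix(montage[match(c(goodn, bad), montage$channel),
                           c("nx", "ny", "nz")])
  pos <- pos / sqrt(rowSums(pos^2))
  ng <- length(goodn)
  cos_gg <- tcrossprod(pos[seq_len(ng), , drop = FALSE])
  cos_bg <- tcrossprod(pos[-seq_len(ng), , drop = FALSE],
                       pos[seq_len(ng), , drop = FALSE])
  G <- spline_g(pmin(pmax(cos_gg, -1), 1)) + diag(lambda, ng)
  Gb <- spline_g(pmin(pmax(cos_bg, -1), 1))
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  V <- rbind(t(data[, goodn, drop = FALSE]), 0)
  sol <- solve(A, V)
  t(cbind(Gb, 1) %*% sol)
}

# ---------------------------------------------------------------------------
# Welch PSD / band power

#' Welch power spectral density
#'
#' Hann-tapered segments of `window_sec` with 50% overlap, one-sided
#' density scaling. Columns of `x` are independent signals sharing the
#' estimate grid.
#'
#' @param x Numeric vector or samples x signals matrix.
#' @param fs Sampling rate, Hz.
#' @param window_sec Welch window length, seconds (default 0.25 s, giving at
#'   least two cycles of 4 Hz per window).
#' @return List with `freq` and `psd` (frequencies x signals).
#' @export
welch_psd <- function(x, fs, window_sec = 0.25) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  L <- round(fs * window_sec)
  stopifnot(nrow(x) >= L)
  hop <- max(1, floor(L / 2))
  starts <- seq(1, nrow(x) - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)
  u <- sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + L - 1), , drop = FALSE] * w
    sp <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + (Mod(sp)^2)
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided doubling: every bin except DC and (for even L) Nyquist
  dbl <- if (L %% 2 == 0) 2:(nf - 1) else 2:nf
  psd[dbl, ] <- 2 * psd[dbl, ]
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd)
}

#' Mean band power from the Welch PSD
#'
#' @inheritParams welch_psd
#' @param band `c(low, high)` Hz, inclusive.
#' @return Numeric vector, one band power per column of `x`
#'   (power = sum of in-band PSD bins x bin width).
#' @export
band_power_welch <- function(x, fs, band = c(4, 8), window_sec = 0.25) {
  p <- welch_psd(x, fs, window_sec)
  df <- p$freq[2] - p$freq[1]
  sel <- p$freq >= band[1] & p$freq <= band[2]
  colSums(p$psd[sel, , drop = FALSE]) * df
}

# ---------------------------------------------------------------------------
# Epoching and measures

#' Epoch a cleaned recording around saccade onsets
#'
#' One epoch per non-excluded trial, spanning [-500, +500) ms around the
#' first-saccade onset (exactly one second; 500 samples at 500 Hz). Epochs
#' whose span exceeds the recording are dropped with a warning. Epochs with
#' peak-to-peak amplitude above `cfg$reject_ptp_uv` on any scalp channel are
#' flagged rejected and excluded from measures; the rejection fraction is
#' stored.
#'
#' @param clean A preprocessed `eeg_recording`.
#' @param trials [build_trial_records()] output (needs `saccade_onset_ms`).
#' @param session The session table (for per-trial Gap windows).
#' @param cfg A [preproc_config()].
#' @param pad_ms Extra context kept on each side for time-frequency charts.
#' @return An `epoch_set`: list with `data` (epochs x channels x samples,
#'   padded), `times_ms`, `core` (index of the [-500, 500) window within the
#'   padded axis), `info` (per-epoch trial link), `rejected`, `gap_windows`.
#' @export
epoch_around_saccades <- function(clean, trials, session,
                                  cfg = preproc_config(), pad_ms = 0) {
  fs <- clean$sfreq
  keep <- trials$outcome %in% c("correct", "error") & !is.na(trials$saccade_onset_ms)
  tr <- trials[keep, , drop = FALSE]
  half <- 500 + pad_ms
  n_samp <- round(fs * (500 + pad_ms) * 2 / 1000)
  times <- (seq_len(n_samp) - 1) / fs * 1000 - half
  onset_idx <- round(tr$saccade_onset_ms / 1000 * fs) + 1
  lo <- onset_idx - round(half / 1000 * fs)
  hi <- lo + n_samp - 1
  inside <- lo >= 1 & hi <= nrow(clean$data)
  if (any(!inside)) {
    warning(sum(!inside), " epochs extend past the recording and were dropped")
    tr <- tr[inside, , drop = FALSE]; lo <- lo[inside]; hi <- hi[inside]
  }
  n_ep <- nrow(tr)
  arr <- array(NA_real_, c(n_ep, ncol(clean$data), n_samp),
               dimnames = list(NULL, clean$ch_names, NULL))
  for (e in seq_len(n_ep))
    arr[e, , ] <- t(clean$data[lo[e]:hi[e], , drop = FALSE])
  eeg <- clean$ch_types == "eeg"
  core <- which(times >= -500 & times < 500)
  ptp <- apply(arr[, eeg, core, drop = FALSE], 1, function(m)
    max(apply(m, 1, function(v) diff(range(v)))))
  rejected <- ptp > cfg$reject_ptp_uv
  key <- paste(tr$run, tr$trial)
  skey <- paste(session$run, session$trial)
  gaps <- session$gap_on[match(key, skey)] + 250  # second half of the Gap
  structure(list(data = arr, times_ms = times, core = core, sfreq = fs,
                 ch_names = clean$ch_names, ch_types = clean$ch_types,
                 info = tr, rejected = rejected,
                 rejection_fraction = mean(rejected),
                 gap_windows = cbind(start = gaps, end = gaps + 250)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%.1f%% rejected), %d channels, %d samples at %g Hz\n",
              nrow(x$info), 100 * x$rejection_fraction,
              dim(x$data)[2], dim(x$data)[3], x$sfreq))
  invisible(x)
}

#' Mean ERP amplitude in a window, baseline-corrected
#'
#' Subtracts each epoch's mean over the [-250, 0) ms baseline, then averages
#' the voltage inside `window_ms`. With `channel = "FCz"` and
#' `window_ms = c(70, 160)` this is the ERN surrogate; with `"Pz"` and
#' `c(200, 500)` the Pe surrogate.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel name.
#' @param window_ms `c(start, end)` ms relative to saccade onset.
#' @param baseline_ms Baseline window, default `c(-250, 0)`.
#' @return Numeric vector, one value per retained epoch (rejected epochs get
#'   `NA`).
#' @export
erp_mean_amplitude <- function(epochs, channel, window_ms,
                               baseline_ms = c(-250, 0)) {
  ic <- match(channel, epochs$ch_names)
  stopifnot(!is.na(ic))
  t <- epochs$times_ms
  wb <- t >= baseline_ms[1] & t < baseline_ms[2]
  ww <- t >= window_ms[1] & t < window_ms[2]
  stopifnot(any(wb), any(ww))
  x <- epochs$data[, ic, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- rowMeans(x[, ww, drop = FALSE]) - rowMeans(x[, wb, drop = FALSE])
  out[epochs$rejected] <- NA_real_
  out
}

#' Theta band power relative to the Gap baseline
#'
#' For every retained epoch, the mean 4-8 Hz Welch band power of the pre
#' ([-500, 0) ms) and post ([0, +500) ms) segments is expressed in dB
#' relative to the same trial's Gap-baseline band power (second 250 ms of
#' the Gap stage, same channel, same estimator):
#' `dB = 10 log10(P_segment / P_gap)`.
#'
#' @param epochs An `epoch_set` (with `gap_windows`).
#' @param clean The preprocessed recording the epochs were cut from (the Gap
#'   baselines are read from it).
#' @param channel Channel name (default `"FCz"`).
#' @param band `c(low, high)` Hz.
#' @return Data.frame: one row per epoch x segment with `run`, `trial`,
#'   `outcome`, `trial_class`, `segment` (`"pre"`/`"post"`), `power_db`.
#'   Epochs with a non-positive baseline are flagged `NA`.
#' @export
theta_power <- function(epochs, clean, channel = "FCz", band = c(4, 8)) {
  ic <- match(channel, epochs$ch_names)
  stopifnot(!is.na(ic))
  fs <- epochs$sfreq
  t <- epochs$times_ms
  pre_i <- t >= -500 & t < 0
  post_i <- t >= 0 & t < 500
  x <- epochs$data[, ic, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p_pre <- band_power_welch(t(x[, pre_i, drop = FALSE]), fs, band)
  p_post <- band_power_welch(t(x[, post_i, drop = FALSE]), fs, band)
  gw <- epochs$gap_windows
  p_gap <- vapply(seq_len(nrow(gw)), function(e) {
    i0 <- round(gw[e, "start"] / 1000 * fs) + 1
    i1 <- i0 + round(0.25 * fs) - 1
    band_power_welch(clean$data[i0:i1, match(channel, clean$ch_names),
                                drop = FALSE], fs, band)
  }, numeric(1))
  db <- function(p) ifelse(p_gap > 0, 10 * log10(p / p_gap), NA_real_)
  info <- epochs$info
  out <- rbind(
    data.frame(info[, c("participant", "run", "trial", "outcome", "trial_class")],
               segment = "pre", power_db = db(p_pre)),
    data.frame(info[, c("participant", "run", "trial", "outcome", "trial_class")],
               segment = "post", power_db = db(p_post)))
  out$power_db[rep(epochs$rejected, 2)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Time-frequency chart of epoch-average power
#'
#' Short-time Welch-style map: Hann windows of `window_sec` centred every
#' `hop_ms` across the epoch, averaged over retained epochs, expressed per
#' frequency in dB relative to the trial-average Gap-baseline PSD. Edge
#' windows are only complete if the epochs were cut with `pad_ms` at least
#' half a window; otherwise coverage shrinks accordingly.
#'
#' @param epochs An `epoch_set`.
#' @param clean The source recording (for Gap baselines).
#' @param channel Channel name.
#' @param freqs Frequencies of interest, Hz.
#' @param window_sec Analysis window, seconds.
#' @param hop_ms Step between window centres, ms.
#' @return List with `times_ms`, `freq`, and `power_db`
#'   (frequencies x times), plus the subset of `freqs` actually resolvable.
#' @export
time_frequency_chart <- function(epochs, clean, channel = "FCz",
                                 freqs = 2:45, window_sec = 0.25,
                                 hop_ms = 25) {
  ic <- match(channel, epochs$ch_names)
  stopifnot(!is.na(ic))
  fs <- epochs$sfreq
  L <- round(fs * window_sec)
  t <- epochs$times_ms
  half_w <- (L / 2) / fs * 1000
  centers <- seq(max(-500, t[1] + half_w), min(500, t[length(t)] - half_w),
                 by = hop_ms)
  keep <- !epochs$rejected
  x <- epochs$data[keep, ic, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)
  u <- sum(w^2)
  nf <- floor(L / 2) + 1
  fgrid <- (seq_len(nf) - 1) * fs / L
  dbl <- if (L %% 2 == 0) 2:(nf - 1) else 2:nf
  fsel <- fgrid >= min(freqs) & fgrid <= max(freqs)
  pmap <- matrix(0, sum(fsel), length(centers))
  for (j in seq_along(centers)) {
    i0 <- which.min(abs(t - (centers[j] - half_w)))
    seg <- x[, i0:(i0 + L - 1), drop = FALSE]
    sp <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))[seq_len(nf), , drop = FALSE]
    ps <- rowMeans(Mod(sp)^2) / (fs * u)
    ps[dbl] <- 2 * ps[dbl]
    pmap[, j] <- ps[fsel]
  }
  # per-frequency baseline: trial-average Gap PSD with the same window
  gw <- epochs$gap_windows[keep, , drop = FALSE]
  icc <- match(channel, clean$ch_names)
  base <- rowMeans(vapply(seq_len(nrow(gw)), function(e) {
    i0 <- round(gw[e, "start"] / 1000 * fs) + 1
    seg <- clean$data[i0:(i0 + L - 1), icc]
    sp <- stats::fft(seg * w)[seq_len(nf)]
    ps <- Mod(sp)^2 / (fs * u)
    ps[dbl] <- 2 * ps[dbl]
    ps[fsel]
  }, numeric(sum(fsel))))
  list(times_ms = centers, freq = fgrid[fsel],
       power_db = 10 * log10(sweep(pmap, 1, base, "/")))
}
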