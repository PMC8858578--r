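# Small deterministic builders shared across test files.

# piecewise trace builder: start from quiet fixation, then apply steps /
# pulses; returns a degree-unit trace at 120 Hz
make_trace <- function(dur_ms = 2000, sfreq = 120, noise = 0.01, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur_ms, by = 1000 / sfreq)
  out <- data.frame(time_ms = t,
                    x = stats::rnorm(length(t), 0, noise),
                    y = stats::rnorm(length(t), 0, noise))
  attr(out, "unit") <- "deg"
  out
}

# add an instantaneous-ish ramp of `amp` degrees on coordinate `coord`
# starting at `onset` lasting `dur` ms (linear ramp; permanent displacement)
add_ramp <- function(trace, onset, dur, amp, coord = "x") {
  tau <- pmin(pmax((trace$time_ms - onset) / dur, 0), 1)
  trace[[coord]] <- trace[[coord]] + amp * tau
  trace
}

# add a go-and-return pulse
add_pulse_tr <- function(trace, onset, dur, amp, coord = "x") {
  tau <- (trace$time_ms - onset) / dur
  pr <- ifelse(tau > 0 & tau < 1, (1 - cos(2 * pi * tau)) / 2, 0)
  trace[[coord]] <- trace[[coord]] + amp * pr
  trace
}

# single-trial session whose Response stage starts late enough for epoching
mini_session <- function(seed = 1, n_trials = 12) {
  generate_session(seed, n_runs = 1, trials_per_run = n_trials)
}

# tiny cleaned recording carrying an arbitrary deterministic signal on FCz,
# for estimator identity checks; all other channels quiet noise
signal_recording <- function(fcz_signal, sfreq = 500, seed = 1,
                             montage = standard_montage("small")) {
  set.seed(seed)
  n <- length(fcz_signal)
  data <- matrix(stats::rnorm(n * nrow(montage), 0, 0.1), n)
  colnames(data) <- montage$channel
  data[, "FCz"] <- fcz_signal
  structure(list(data = data, sfreq = sfreq, montage = montage,
                 ch_names = montage$channel, ch_types = montage$type,
                 t0_ms = 0), class = "eeg_recording")
}
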