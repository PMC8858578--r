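---
title: "Midfrontal theta error monitoring in a saccadic go/no-go task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Midfrontal theta error monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errtheta)
```

# The scientific problem

Error monitoring is the metacognitive process by which the brain detects that
an executed action deviated from the intended one. Its best-established
electrophysiological marker is midfrontal theta: 4-8 Hz EEG oscillations,
maximal at FCz, whose power rises immediately after an erroneous response.
There is also evidence for the converse pattern before the response — reduced
theta while an error is being prepared, consistent with a lapse of
attentional control.

`errtheta` implements, as a tested and reusable pipeline, the analysis needed
to measure both effects in a demanding paradigm: a go/no-go saccade task
whose instructions are facial cues. A happy face with averted gaze cues a
pro-saccade (look where the face looks), a sad averted face an anti-saccade
(look the opposite way), and a straight-ahead gaze — happy or sad — cues
withholding the saccade. Six instructions (2 emotions x 3 gaze directions)
are presented in counterbalanced runs of 84 trials (28 pro, 28 anti, 28
no-go; 14/14 left-right splits within the go classes and 14/14 happy-sad
within no-go). Each trial walks through six stages — Neutral face (1000 ms),
Gap (500 ms), Instruction (750 ms), Fixation (500-1000 ms in 100 ms steps,
drawn uniformly to prevent anticipation), Target (200 ms, a square 8.30
degrees left or right), Response (1500 ms).

Because responses are saccades, response onset is not a key press but must
itself be detected from the eye-tracking trace; and because participants are
fast, most responses are launched already during the Fixation/Target stages
(mean about half a second before the Response stage opens). All EEG measures
are therefore locked to detected saccade onset.

The pipeline has five stages, each exposed as package functions and each fed
by a synthetic-data module with planted ground truth:

1. paradigm generation (`generate_session()`),
2. gaze and EEG simulation (`simulate_gaze()`, `simulate_eeg()`),
3. displacement-threshold saccade detection (`detect_events()`),
4. EEG preprocessing and theta/ERP extraction (`preprocess()`,
   `epoch_around_saccades()`, `theta_power()`, `erp_mean_amplitude()`,
   `time_frequency_chart()`),
5. the subsampled balanced Wilcoxon replication decision
   (`replication_test()`), with effect sizes, normality-gated omnibus tests
   and JZS Bayes factors around it.

# Saccade detection

Detection is purely displacement-based — no velocity threshold anywhere. The
horizontal gaze coordinate (converted from pixels by the exact arctangent
mapping for a 17-inch 1280 x 1024 screen at 60 cm) is segmented into events
and each event is labelled:

* **blink-like** if its vertical amplitude is at least 80% of its horizontal
  amplitude (both coordinates move during a blink);
* **micro-saccade** if the horizontal amplitude is below 4.04 degrees or the
  duration below 15 ms (fixational micro-saccades are classically below 2
  degrees; the working threshold is higher because tower-mounted trackers
  convert small head movements into apparent gaze shifts);
* **rejected-central** if the amplitude passes but the event *ends inside*
  the central area (4.04 degrees radius) — e.g. the return sweep to the
  fixation cross, which must not count as a response;
* **saccade** otherwise.

The event boundaries themselves need a definition the thresholds do not
supply. We use: an event starts at the first sample deviating from the local
fixation level — a trailing 100 ms running median — by more than a noise
band of 3 trailing SDs (floored at 0.02 degrees); the level and band are
then frozen, and the event ends when the trace either returns inside the
band (go-and-return events: micro-saccades, blinks) or stops moving — its
range over a trailing 25 ms falls within the band — as when a saccade lands
on a new fixation point. The frozen-level rule keeps measured amplitudes and
durations faithful to the planted kinematics; a purely rolling band would
truncate long saccades when the rolling SD absorbs the movement itself. Two
consequences are documented rather than hidden: the detected onset lags the
true movement start by the time the displacement needs to exceed the band
(under one sample at low noise), and the detected duration includes the
stabilisation span (a roughly constant ~15-20 ms addition that cancels in
correct-versus-error contrasts).

The test suite holds the detector against an independently coded brute-force
reference on a thousand randomised traces, and against planted ground truth
(100% sensitivity and precision in the low-noise regime).

# Behavioural classification

A trial is **correct** when its first saccade inside the response-eligible
span (Fixation onset to Response-stage end — responses during Fixation are
responses, as the negative mean response timing shows) follows the
instruction, **error** when it violates it (wrong direction on go trials,
any saccade on no-go trials), and **excluded** when no saccade occurred,
since response-locked epochs need an onset. Per participant we report the
relative error rate, the pro/anti/no-go shares of the errors, and mean
response timing, saccade amplitude and duration split by outcome.

# EEG pipeline

Preprocessing follows the standard midfrontal-theta recipe: zero-phase
windowed-sinc FIR band-pass 0.05-45 Hz (Hamming; 3301 taps at 1000 Hz,
applied as a single symmetric convolution so the phase response is exactly
zero — not forward-backward filtering, which squares the magnitude
response), decimation to 500 Hz (safe, the upper edge is far below the new
Nyquist), automated bad-channel flagging (robust z of log variance and log
20-45 Hz power, |z| > 5 — an explicit, reproducible stand-in for visual
inspection), average reference over the good scalp channels (EOG excluded),
an optional caller-supplied artifact-reduction hook (where a
decomposition-based ocular cleanup would run; the package does not
re-implement ICA), and spherical-spline interpolation (stiffness m = 4,
20 Legendre terms, ridge 1e-5) of the flagged channels. A run aborts if FCz
or Pz is flagged, since those carry the measures.

Epochs span [-500, +500) ms around each response-saccade onset — exactly 500
samples at 500 Hz — with peak-to-peak rejection above 150 microvolt
replacing visual trial screening. ERP surrogates are window means after
[-250, 0) ms baseline subtraction: FCz 70-160 ms (ERN) and Pz 200-500 ms
(Pe).

Theta power uses Welch's estimator: 250 ms Hann windows, 50% overlap (at
least two cycles of 4 Hz per window; the estimator is a config argument, so
a multitaper could be swapped in). Each epoch yields a pre ([-500, 0) ms)
and post ([0, +500) ms) mean 4-8 Hz power, expressed as

dB = 10 log10(P_segment / P_gap),

where P_gap is the same-channel, same-estimator band power of the *second*
250 ms of that trial's Gap stage — the first half is too close to the
preceding face stimulus. The baseline is per trial, not per run, for the
same reason. Two numerical notes: (i) the Gap baseline is a single Welch
window, so the log ratio carries a small positive bias (about +0.1 to +0.2
dB at the default noise levels) that is *shared by all four condition cells*
and cancels exactly in every correct-versus-error contrast the statistics
consume; (ii) with 250 ms windows the 4 and 8 Hz bins collect some
low-frequency leakage, which is why the simulator calibrates planted powers
against the estimator itself rather than against idealised spectra.

`time_frequency_chart()` produces the epoch-average short-time map (2-45 Hz,
dB against the per-frequency Gap baseline) used for visual inspection of the
pre/post theta pattern; epochs can be cut with padding so the edge windows
are complete.

# The replication statistic

Errors are rare (about 5% of trials), so correct trials outnumber error
trials roughly twenty-fold and a single pooled test would be dominated by
the majority class. The decision procedure instead draws 20 subsamples of
correct trials — per participant, each subsample is exactly as large as that
participant's error set, and contains exactly as many pro-saccade trials
(anti-saccade and no-go trials demand inhibitory control; pro trials do
not, so the mix is matched rather than randomised). Draws are without
replacement within an iteration and independent across iterations. Each
iteration runs a two-sided paired Wilcoxon signed-rank test across
participants on (mean error minus mean correct-subsample); the contrast is
declared significant when at least 80% of the 20 iterations — 16 of 20 —
reach p <= 0.05. Per iteration we report the signed standardised statistic
Z (normal approximation with tie and continuity corrections, signed by the
direction of the rank mass; p-values from `stats::wilcox.test`, exact below
10 untied pairs) and the effect size r = Z / sqrt(N), N the number of
participants.

The rule is deliberately conservative: under the null each iteration is a
valid 5% test, and demanding 16 simultaneous rejections pushes the aggregate
false-positive rate far below 5% even though the iterations are positively
correlated (they share the error set). The suite measures this by
simulation rather than assuming it.

Around the decision rule sit the supporting tests: a Shapiro-Wilk gate
(alpha .05; degenerate samples route conservatively to the nonparametric
branch) choosing repeated-measures ANOVA (partial eta squared =
SS_effect/(SS_effect + SS_error)) versus Friedman for the three error types,
with Friedman always used below 10 participants; and a paired JZS Bayes
factor (Cauchy prior, scale sqrt(2)/2, computed by numerical integration of
the standard g-prior marginal) reported explicitly as both BF10 and BF01
with the conventional evidence labels, because a Bayes factor quoted without
its direction is ambiguous.

# The synthetic-data module

The generator's defaults are the study conditions, not tuning knobs:

* behaviour: 5.21% error probability in every class; response latency
  (relative to Response onset) N(-497, 628) ms on correct and N(-449, 572)
  ms on error trials, truncated to the response-eligible span — note the
  truncation raises the *realised* mean latency to about -230 ms, since a
  normal with that SD places substantial mass before the earliest physically
  eligible moment (real latency distributions are skewed; the generator
  keeps the normal for simplicity and documents the consequence); saccade
  amplitude N(10.50, 2.59) / N(9.53, 2.41) degrees and duration
  N(70.6, 20.9) / N(56.8, 15.6) ms for correct/error, floored at 4.5
  degrees and 25 ms so every planted response is physically detectable;
  micro-saccades at 1/s (uniform 0.3-1.8 degrees) and blink-like vertical
  excursions at 0.15/s during the pre-response stages;
* EEG: a 6 Hz theta carrier at FCz with a Gaussian spatial profile, stepped
  around each planted saccade onset to realise the four dB cells —
  pre-correct 1.58, pre-error 1.26, post-correct 1.35, post-error 2.31 dB
  relative to the Gap baseline — over a 1/f background, with EOG channels
  carrying the saccade/blink waveforms and a distance-decaying leakage into
  the scalp channels (what a decomposition-based cleanup would remove).

Planted amplitudes are calibrated against the package's own Welch estimator
(`band_capture`, the phase-averaged fraction of a sinusoid's power the
estimator assigns to 4-8 Hz, and an estimator-referenced measurement of the
background's in-band contribution), so "planting x dB" means the estimator
is expected to read x dB.

Two noise parameters were fixed once, by a design power calculation made
before the acceptance checks were ever run, and not revisited: the
background's 4-8 Hz power at FCz is 1% of the baseline theta band power,
and each planted segment's theta power is jittered by 0.25 dB (SD) across
trials. With ~10 error trials per participant (5% of 200 epochs), those
values make the per-participant paired contrast of the smallest planted
effect (0.32 dB pre-response) about one within-participant SD, which is the
regime in which the statistical machinery — not estimator noise — is under
test. This idealises real data in a stated way: single-trial theta in real
EEG varies far more, phase-jitters, and coexists with non-ocular artifacts;
passing the recovery tests therefore validates the pipeline's correctness
and the decision rule's operating characteristics, not the claim that any
real dataset has effects this clean. The segment-level study driver
(`simulate_theta_epochs()`, `theta_study()`) generates exactly the three
signal segments per epoch the theta measure consumes, at the analysis rate,
and feeds the same estimator and the same replication code as the full
chain; the continuous-recording plumbing (filtering, epoching, referencing,
interpolation) is validated separately end-to-end at smaller scale. That
split is what makes 100-replicate power studies and 500-replicate type-I
studies run in minutes on one CPU.

Problem sizes used by the automated checks: the oracle-equivalence sweep
uses 1000 two-second traces; the power study 100 replicates of 19
participants x 200 epochs; the type-I study 500 replicates of 19
participants x 50 epochs; the end-to-end EEG checks single participants
with 12-48-trial runs on a 16-channel subset of the montage (the layout
always keeps FCz, Fpz and Pz).

# Design choices on open points

* **Counterbalancing** is enforced exactly per run (the only reading
  consistent with exact 28/28/28 and 14/14 counts), via a seeded uniform
  permutation; no-go target side is a fair coin.
* **Response-eligible span** runs from Fixation onset: the observed mean
  response precedes the Response stage, so earlier saccades are responses;
  saccades during the Instruction stage are not.
* **"Mean activity" of the Gap baseline** is interpreted as band power
  (config-switchable in principle to broadband amplitude; band power is the
  quantity the dB ratio needs).
* **Gap baselines are per trial**, not averaged across trials before the
  ratio: the stated reason for discarding the Gap's first half is
  trial-specific contamination, which implies a trial-level baseline.
* **Subsample draws are independent across iterations** (overlap allowed):
  nothing in the procedure forbids it and it is the simplest faithful
  reading; pro-count rounding goes half-toward-fewer-pro, deterministically.
* **Erroneous no-go saccade direction** is recorded but used nowhere.
* **Bayes factor direction**: both BF10 and BF01 are always reported; the
  evidence label names the hypothesis it favours.
* **Montage coordinates are synthetic** — a schematic 10-10-style spherical
  grid built in code and used consistently by simulation and preprocessing;
  no claim of anatomical fidelity is made or needed.

# Known limitations

* The simulator does not model phase-jittered or bursty theta, spatially
  correlated background noise, drifting electrode impedances, or gaze
  sampling jitter (missing samples are injectable; jitter is not).
* ERN/Pe deflections are not planted; the ERP functions are validated by
  construction (baseline identities, planted window deflections), matching
  the empirical finding that this paradigm's ERPs are weak.
* The automated bad-channel and epoch-rejection criteria are reproducible
  stand-ins for human screening; on real data their thresholds deserve
  inspection.
* Detected durations include the stabilisation lag and detected onsets the
  band-crossing lag; both are near-constant offsets, harmless for
  contrasts, visible in absolute comparisons.
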