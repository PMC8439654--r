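---
title: "Methods: offline corticostriatal sleep analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offline corticostriatal sleep analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corticosleep)
```

# Scope and model

`corticosleep` analyses multiday paired recordings from primary motor
cortex (M1) and dorsolateral striatum (DLS) taken around daily skilled
reach training: a 2–3 h *pre-training* rest period, a training block, and
a 2–3 h *post-training* rest period per day. The pipeline asks how
corticostriatal functional connectivity evolves *offline* (across rest
periods and nights) and how NREM sleep rhythms — sleep spindles, slow
oscillations (SOs) and delta waves — organise short-latency M1→DLS spike
transmission.

Every stage consumes a plain `session` container (LFP channels with
region labels, sorted units, period boundaries, per-10 s movement flags,
reach-trial touch times) and the package ships a synthetic-session
generator that plants ground truth for each stage, so the entire pipeline
is verifiable without the original recordings.

# Sleep staging

The mean M1 LFP is segmented into non-overlapping 10 s epochs; per epoch
we compute multitaper delta power (mean PSD, 1–4 Hz) and a theta ratio.
The staging rules use the *within-period means* as thresholds:

* **NREM**: delta power above its mean and no movement;
* **REM**: theta ratio above its mean and delta below its mean;
* otherwise **wake**;

applied in that order, followed by reclassifying every NREM/REM run
shorter than six epochs (60 s) as wake.

Numerical choices:

* **Theta ratio as a band-integral ratio.** The ratio of 5–10 Hz to
  2–15 Hz *band power* (sums over the 0.1 Hz grid) lies in [0, 1] and
  equals the bandwidth ratio 5/13 for white noise; a ratio of mean PSDs
  would not. The classification is monotone-equivalent either way.
* **Multitaper parameters**: time–bandwidth 3 with 5 Slepian tapers
  (configurable), 10 s windows (0.1 Hz grid). Tapers are computed from
  the tridiagonal Slepian eigenproblem; long windows are
  spline-interpolated from a 1024-point solution and re-orthonormalised.
  Windows are demeaned so DC offsets cannot leak through taper
  sidelobes.
* **REM and movement.** The staging rule for REM carries no movement
  condition; it is implemented exactly as stated and this is flagged
  here because quiet wake with relatively high theta can therefore be
  labelled REM. The mean-threshold scheme also assumes the period
  contains a genuine mixture of states — in a period that is almost
  entirely one state, the thresholds converge to that state's own mean
  and accuracy necessarily degrades. This is a property of the method,
  not of the implementation.

# NREM rhythm detection

**Spindles**: mean M1 LFP is band-passed 10–16 Hz (zero-phase 3rd-order
Butterworth); the envelope is the Gaussian-smoothed (s.d. 40 ms,
configurable) Hilbert magnitude. Thresholds come from the NREM envelope:
a candidate is a run of ≥ 500 ms above mean + 1.5 s.d. containing at
least one sample above mean + 2.5 s.d.; events closer than 300 ms are
merged; events whose peak lies outside NREM are dropped. Both thresholds
are applied to the envelope; `use_power = TRUE` exposes the
squared-envelope reading of the ambiguous "power" wording.

**SOs and delta waves**: 0.1 Hz high-pass (2nd order) then 4 Hz low-pass
(5th order), both zero-phase. Every positive-to-negative zero crossing in
NREM yields a candidate (previous peak, following trough, surrounding
negative-to-positive crossings; span = time between the latter).
Percentile pools are all candidates of the period, with
linear-interpolation quantiles. SO: peak in the top 15 % of peaks AND
trough in the deepest 40 % AND 0.3 s < span ≤ 1 s. Delta: peak in the
bottom 85 % AND trough in the deepest 40 % AND span > 0.25 s. SO takes
precedence, so classes are disjoint. The "upstate peak" landmark is the
filtered-signal positive peak (polarity convention configurable, since
depth-LFP polarity varies).

**Nesting**: spindle delay to the most recent preceding SO down-crossing;
≤ 1 s → SO-nested, ≥ 5 s → non-SO-nested, otherwise (including no
preceding SO) unclassified.

**Rhythm modulation** of a unit: 10 ms PETH from −2 to +2 s around the
landmark; modulation = (min-to-max range in −0.5…0.5 s) / (range in
−1.5…−0.5 s); significance = real modulation above the 99th percentile of
1000 bin-permutation shuffles.

# LFP coherence

Channels are common-median referenced within region, z-scored over the
session, and obviously noisy channels (s.d. > 5× the median channel
s.d.) dropped — an automated stand-in for manual electrode rejection.
Coherence is computed per 10 s NREM window with the same multitaper
settings and the per-window magnitudes are averaged (`average =
"complex"` exposes the alternative of averaging complex coherency; with
K = 5 tapers the magnitude average carries a positive small-sample bias
at low true coherence, which is why band values should only be compared
against estimates with matching window counts). A pair is
"high-coherence" when its mean 4–8 Hz NREM coherence exceeds 0.6
(strictly).

Across days, the online change is post − pre within a day and the
offline change is next-day pre − post. The total change is defined as
last-pre − first-pre, which exactly equals the sum of all offline changes
plus all online changes except the last day's (a telescoping identity the
tests assert); means over days use all changes. Trends use a ±0.025 dead
zone on the total change.

Phase differences use a zero-phase windowed-sinc FIR band-pass (order =
three cycles of the low cutoff) and the analytic-signal phase, collected
over NREM samples and summarised by circular mean and resultant.

# Spike-phase locking

DLS spike phases are read off the 4–8 Hz analytic phase of each M1
channel at NREM spike times. Locking is summarised by the circular
standard deviation, `cSD = sqrt(-2 log Rbar)`, computed from raw phases —
the 20-bin histogram is descriptive only (whether the original binned
first is unknowable; raw phases are statistically cleaner). The Rayleigh
test uses the standard small-sample-corrected p approximation and is
flagged untestable below n = 5.

# Short-latency coupling (interval jitter)

Spiking is binned at 1 ms and concatenated over analysis intervals with a
guard gap so no spike pair spanning two intervals is ever counted. The
cross-correlogram (CCG) is centred on DLS spiking: positive lags mean DLS
after M1. The coupling statistic is the mean CCG over lags 1–15 ms,
expressed *per M1 reference spike* — this normalisation makes the
statistic invariant to background-rate scaling and linear in the planted
excess-spike probability, and it cancels in the real-vs-surrogate
comparison.

Surrogates jitter each DLS spike uniformly within a 50 ms window centred
on the spike, clipped at interval boundaries (spikes near concatenation
edges never leak across bouts). A pair is *coupled* when the real
statistic exceeds the 99th percentile (linear interpolation) of 1000
surrogate statistics, evaluated on the first 5 NREM minutes of pre plus
the first 5 of post.

Transmission *magnitude* subtracts the surrogate expectation from the
real CCG. Rather than averaging 1000 Monte Carlo surrogate CCGs, the
expectation is computed in closed form by smearing each DLS spike over
its allowed jitter offsets — the exact n→∞ limit of that average, with
zero Monte Carlo error; the Monte Carlo ensemble is still drawn where a
distribution (the 99th percentile) is required. Condition magnitudes
(NREM vs wake; spindle/SO/delta windows of ±0.5 s around landmarks;
period halves; peri-spindle 30 s bins at the printed edges −91/−61/−31/−1
and 1/30/31/61/61/91 s, taken as half-open intervals, baseline-subtracted
by the first bin) recompute the surrogate expectation on the condition's
own intervals.

# Population trajectories

DLS spiking is binned at 100 ms from −5 to +5 s around pellet touch
(half-open bins; touch sits on the bin 50/51 boundary). PCA is fit on the
trial-concatenated time-bins × units matrix (per-unit mean centring, no
variance scaling — counts share units); trajectories are the projections
of the −1…+1 s sub-window on the first three components. Each component
is predicted from the preceding 1.5 s of all M1 units' counts by a
separate linear model under 5-fold cross-validation with contiguous trial
blocks (guards against leakage through slow drift); the score is the mean
Pearson correlation between held-out predictions and actual trajectories.
The baseline window (−5…−4 s) uses identical machinery; its M1 tensor
must extend to −6.5 s so every predicted bin has a full history.

The task-modulation index uses 25 ms bins over ±5 s, trial-averaged and
z-scored; index = Σ|z| over (−1, +0.5) s divided by Σ|z| over
(−3.5, −2) s (60 bins each).

# Reach kinematics

Velocity profiles are frame-to-frame first differences (no smoothing; a
smoother can be added by the caller) over 500 ms before to 500 ms after
pellet touch, resampled to 100 samples/s when frame rates differ. Each
day's mean profile is correlated with the last day's ("template") mean,
separately in x and y, then averaged; the total change excludes the
template day (second-to-last minus first). The AP5/saline effect is the
difference in mean day-to-day change between labels, tested by 10,000
label reshuffles; the raw percentile is reported together with the
two-sided `2·min(q, 1−q)` since only a percentile is specified.
Day-to-day changes are consecutive differences of the per-day
correlations. The coherence–behaviour relation z-scores day series within
animal and reports pooled Pearson and partial correlations (partial via
the residual-correlation identity).

# The synthetic world

The generator states one concrete world and the tests measure the
pipeline inside it:

* **Sleep architecture**: alternating bouts with exponential dwells
  (means: wake 240 s, NREM 240 s, REM 120 s; NREM→REM probability 0.5);
  sleep bouts are ≥ 60 s *by construction*; 10 s quantisation. These
  dwell means keep period-level state compositions near a balanced
  mixture — mean-threshold staging degrades by design when one state
  dominates, so accuracy criteria are asserted pooled across sessions.
* **LFP**: per state, a sum of band-limited Gaussian components (delta
  0.5–4 Hz, theta 5–10 Hz) and 1/f^1.5 background with state-specific
  gains (delta-dominated NREM, theta-dominated REM, 1/f-dominated quiet
  wake). Wake epochs carry movement flags with probability 0.8.
* **Spindles** are flat-top 12 Hz bursts (600 ms, 20 ms cosine ramps).
  Their amplitude parameter is in s.d. units *of the realized NREM
  spindle-band envelope* — the same scale the detector's thresholds use.
  Because the planted events themselves inflate that envelope's moments,
  the amplitude is solved as a fixed point at generation time. This
  matters: calibrating naively against the event-free background makes
  "4 s.d." land below the effective detection threshold and caps recall
  around 0.86.
* **SO/delta waves** are single biphasic cycles (corner-softened to keep
  spindle-band leakage out) scaled against the low-frequency NREM floor
  so their peaks/troughs land in the intended percentile ranges. A
  configurable fraction of spindles is planted 0.3–0.8 s after an SO
  down-crossing (SO-nested) and the rest ≥ 6 s away.
* **Spikes**: M1 units are inhomogeneous Poisson (multiplicative spindle
  gain, von Mises 4–8 Hz phase gain); coupled DLS units receive an extra
  spike at 6 ms (+ ≤ 2 ms jitter) per M1 spike with the planted excess
  probability (synaptic-copy model — the ground-truth lag is unambiguous,
  unlike common drive), optionally boosted during spindles and for 30 s
  after SO-nested spindles.
* **Coherence** is planted by adding a shared 4–8 Hz component during
  NREM at a per-day, per-period SNR; the asymptotic coherence is
  snr/(1+snr). The component is gated to NREM because the phenomenon
  being modelled is an NREM-sleep coupling, and leaving it on during
  wake distorts the staging features.
* **Behaviour**: day mean velocity profiles are convex blends between a
  fixed smooth noise profile and a template, with blend weight growing
  per day and frozen on AP5 days; trials add smooth velocity noise.

What a green test does *not* establish: the generator is stationary
within states, Gaussian, and free of electrode artifacts, volume
conduction, cell-type structure and waveform issues; real recordings
violate all of these. Detector false positives on Gaussian background are
an intrinsic excursion property — at population scale a small fraction of
400 ms or sub-threshold bursts will ride background fluctuations over the
criteria, which is why single-burst rejection cases are asserted
deterministically in quiet background.

# Runtime scaling

Tests and the acceptance suite run the stated world at 250 Hz with
minutes-long periods instead of 1 kHz × 2–3 h. Scaling affects only
runtime: all rule constants (thresholds, window lengths, percentiles,
bout rules), rates and effect sizes are the stated ones.

# Known limitations

* Directed measures (Granger, transfer entropy) are out of scope; the
  CCG lag convention is directional but not causal.
* REM-specific analyses are not provided (REM time is typically
  insufficient in this preparation).
* The coherence summary averages magnitudes across windows; comparisons
  across conditions with very different window counts inherit the
  magnitude bias.
* Spike sorting, pose tracking and cell-type classification are inputs,
  not package functionality.
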