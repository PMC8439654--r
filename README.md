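# corticosleep

Offline-sleep analyses for multiday paired recordings from rat primary
motor cortex (M1) and dorsolateral striatum (DLS) around skilled reach
training. The package is for systems neuroscientists who record LFP and
sorted single units across daily pre-training and post-training rest
periods and want to quantify how corticostriatal functional connectivity
changes offline and how NREM rhythms organise it.

## What it computes

* **Sleep staging** — wake/NREM/REM in 10 s epochs from multitaper mean
  M1 LFP features: delta power (1–4 Hz) and theta ratio (5–10 / 2–15 Hz)
  thresholded at their within-period means, plus movement; sleep bouts
  under 60 s are reclassified as wake. A 1–4 Hz power curve,
  duration-normalised, serves as a sleep-depth proxy.
* **NREM rhythms** — sleep spindles (10–16 Hz envelope, 2.5 / 1.5 s.d.
  dual threshold, ≥ 500 ms, < 300 ms merge), slow oscillations and delta
  waves (zero-crossing candidates; top-15 % peak / deepest-40 % trough
  percentile rules with span limits), SO-nesting of spindles (≤ 1 s vs
  ≥ 5 s delay), and shuffle-tested spiking modulation (PETH range ratio
  vs 1000 bin permutations, 99th percentile).
* **LFP coherence** — common-median referencing, z-scoring, multitaper
  (TW = 3, K = 5) coherence magnitude in 10 s NREM windows for every
  M1 × DLS electrode pair; 4–8 Hz band means with the > 0.6
  high-coherence flag; online (pre→post) vs offline (post→next-day pre)
  decomposition with trend classes; 4–8 Hz phase differences.
* **Spike-phase locking** — circular s.d. `sqrt(-2 log Rbar)` of DLS
  spike phases on the 4–8 Hz M1 analytic phase, Rayleigh tests, and the
  per-channel cSD-vs-coherence comparison.
* **M1→DLS coupling** — 1 ms cross-correlograms centred on DLS spiking
  (positive lag = DLS after M1); 50 ms interval-jitter surrogates; a pair
  is coupled when the mean 1–15 ms CCG exceeds the surrogate 99th
  percentile; jitter-normalised transmission magnitudes by state, NREM
  rhythm, period half, and six 30 s peri-spindle bins split by
  SO-nesting.
* **Population trajectories** — PCA of DLS trial tensors (100 ms bins,
  ±5 s around pellet touch), trajectories on the first three components
  over ±1 s, predicted from 1.5 s of M1 history with 5-fold
  cross-validated linear models; per-unit task-modulation indices.
* **Reach kinematics** — per-trial velocity profiles (±500 ms around
  pellet touch), per-day correlation with the last-day template, total
  learning change, AP5/saline permutation test (10,000 reshuffles), and
  the coherence–behaviour (partial) correlation.
* **Synthetic sessions** — `synth_config()` + `simulate_session()` plant
  sleep architecture, rhythms, coherence drift, coupled Poisson spike
  trains (~6 ms lag) and converging reach kinematics with full ground
  truth, so every stage above is testable end to end.

## Worked example

```r
library(corticosleep)

cfg <- synth_config(seed = 7, sampling_rate = 250,
                    period_s = c(pre = 1200, train = 300, post = 1200),
                    n_m1_channels = 3, n_dls_channels = 3,
                    n_m1_units = 4, n_dls_units = 4, n_trials = 20)
sim <- simulate_session(cfg, day = 1)
s <- sim$session
s
#> <session synth_d01 day 1: 6 ch (3 M1 / 3 DLS), 250 Hz, 2700 s, 8 units, 20 trials>

hyp <- stage_period(s, "pre")
hyp
#> <hypnogram pre: 120 epochs x 10s | wake 81, NREM 33, REM 6>
mean(hyp$labels == sim$truth$hyp_pre$labels)   # planted-state accuracy
#> [1] 1

m1 <- mean_region_lfp(s, "M1")
sp <- detect_spindles(m1, s$sampling_rate, hyp)
nrow(sp); length(sim$truth$events_pre$spindle)  # detected vs planted
#> [1] 22
#> [1] 22

ver <- detect_coupled(s$units[[1]]$spike_times,       # planted M1 unit
                      s$units[[5]]$spike_times,       # its DLS partner
                      stage_period(s, "pre"), stage_period(s, "post"),
                      seed = 1)
ver$coupled; ver$real_stat; ver$q99
#> [1] TRUE
#> [1] 0.01060986
#> [1] 0.00628655
```

The coupling verdict reads: over the first 5 NREM minutes of pre plus
post, the pair's mean 1–15 ms cross-correlogram value per M1 spike
(0.0106) exceeds the 99th percentile of 1000 jitter surrogates (0.0063),
so the planted 6 ms, 10 %-excess connection is recovered.

Numbers above are what the code prints at these exact settings; staging
accuracy and detection counts vary with `seed`.

## Acceptance

Acceptance for this build is property-based (null calibration and power
of the jitter test, detector recall/precision on planted rhythms, rule
exactness, estimator-vs-oracle agreement, end-to-end smoke); it runs as
`tests/testthat/test-acceptance.R`. The report script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs a reduced end-to-end smoke of the installed package and writes the
acceptance-target report — an empty JSON object, since this build's
target list is empty (the source analyses' printed values require the
original multi-animal recordings).

## Command line

A thin CLI ships in `inst/cli/corticosleep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/corticosleep.R", package="corticosleep"))')" \
  simulate --seed 1 --out synth/
# ... validate <dir> | stage <dir> --period pre | rhythms <dir> | coherence <dir>
```

## Session directory format

`write_session()` / `read_session()` use a plain directory:
`metadata.json`, `lfp.f32` (little-endian float32, row-major
channels × samples), `units.csv`, `trials.csv`, `movement.csv` —
inspectable, diffable, language-neutral. Spike times round-trip exactly;
LFP to float32 precision.
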