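## Synthetic multiday session generator with planted ground truth.
##
## The generator emulates the statistical structure the analyses assume:
## state-dependent LFP spectra (delta-dominated NREM, theta-dominated REM,
## broadband wake), spindles / slow oscillations / delta waves injected
## only in NREM, Poisson spike trains with short-latency (~6 ms) M1->DLS
## excess-spike coupling and rhythm/phase rate modulation, per-day common
## 4-8 Hz signal injection controlling LFP coherence, and reach velocity
## profiles converging to a template (optionally frozen by AP5). Every
## planted quantity is returned as ground truth.

#' Synthetic-session configuration
#'
#' Defaults state the recording conditions the analyses were designed for:
#' 1 kHz LFP, 2 h pre/post periods, ~12 Hz spindles of ~0.6 s at 4 s.d.,
#' 6 ms M1->DLS lag. Tests and the acceptance script pass scaled-down
#' durations/sampling rates; thresholds and effect sizes stay fixed.
#'
#' @param seed master seed; all per-day/per-period streams derive from it.
#' @param sampling_rate LFP rate, Hz.
#' @param period_s named durations (s) for `pre`, `train`, `post`.
#' @param n_days number of training days.
#' @param n_m1_channels,n_dls_channels LFP channel counts per region.
#' @param state_dwell mean bout lengths (s) for `wake`, `NREM`, `REM`;
#'   a zero suppresses the state entirely.
#' @param rhythm_rates events per NREM minute for `spindle`, `SO`, `delta`.
#' @param nested_fraction fraction of spindles planted 0.3-0.8 s after an
#'   SO down-crossing (the SO-nested class); the rest are kept >= 6 s from
#'   any planted SO.
#' @param spindle_freq,spindle_dur_s,spindle_amp_sd spindle centre
#'   frequency (Hz), duration (s) and amplitude in NREM-envelope s.d.
#'   units.
#' @param so_span_s,delta_span_s planted event spans (s).
#' @param n_m1_units,n_dls_units unit counts.
#' @param m1_rate,dls_rate base firing rates (Hz, recycled per unit).
#' @param coupling data.frame (`m1`, `dls`, `lag_s`, `excess_prob`):
#'   1-based unit indices within each region; empty for no coupling.
#' @param spindle_mod_depth multiplicative M1 rate gain inside spindles.
#' @param phase_kappa von Mises concentration of M1 spiking on the 4-8 Hz
#'   phase (0 = none).
#' @param spindle_coupling_gain multiplies `excess_prob` within +/- 0.5 s
#'   of spindle peaks.
#' @param nested_boost_prob additive excess probability in the 30 s after
#'   an SO-nested spindle (plants the post-spindle transmission boost).
#' @param coherence_snr per-day, per-period common-signal SNR: matrix
#'   `n_days x 2` (columns pre, post) or a single number.
#' @param n_trials,frame_rate reach trials per day and camera rate.
#' @param conv_start,conv_rate template blend weight on day 1 and its
#'   per-day increment; `ap5_days` freezes the weight on those days.
#' @param trial_noise_sd velocity noise per trial (units/s).
#' @param peak_velocity_trend per-day multiplicative amplitude trend.
#' @export
synth_config <- function(seed = 1L,
                         sampling_rate = 1000,
                         period_s = c(pre = 7200, train = 1800, post = 7200),
                         n_days = 2L,
                         n_m1_channels = 4L, n_dls_channels = 4L,
                         state_dwell = c(wake = 240, NREM = 240, REM = 120),
                         rhythm_rates = c(spindle = 5, SO = 4, delta = 4),
                         nested_fraction = 0.4,
                         spindle_freq = 12, spindle_dur_s = 0.6,
                         spindle_amp_sd = 4,
                         so_span_s = 0.6, delta_span_s = 0.5,
                         n_m1_units = 8L, n_dls_units = 8L,
                         m1_rate = 5, dls_rate = 3,
                         coupling = data.frame(m1 = 1L, dls = 1L,
                                               lag_s = 0.006,
                                               excess_prob = 0.1),
                         spindle_mod_depth = 2,
                         phase_kappa = 0.5,
                         spindle_coupling_gain = 1,
                         nested_boost_prob = 0,
                         coherence_snr = 1,
                         n_trials = 100L, frame_rate = 75,
                         conv_start = 0.3, conv_rate = 0.1,
                         ap5_days = integer(0),
                         trial_noise_sd = 0.5,
                         peak_velocity_trend = 0) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$coupling$excess_prob >= 0),
            all(cfg$coupling$excess_prob <= 1),
            all(cfg$coupling$lag_s >= 0),
            all(cfg$rhythm_rates >= 0), cfg$sampling_rate > 0)
  if (length(cfg$coherence_snr) == 1)
    cfg$coherence_snr <- matrix(cfg$coherence_snr, cfg$n_days, 2,
                                dimnames = list(NULL, c("pre", "post")))
  structure(cfg, class = "cs_synth_config")
}

## deterministic sub-seed below 2^31, keyed by (seed, day, period, stream)
derive_seed <- function(seed, day, period, stream) {
  p <- match(period, c("pre", "train", "post", "behavior"))
  s <- match(stream, c("hyp", "lfp", "spk", "beh", "mov"))
  as.integer((as.numeric(seed) * 2654435 + day * 97003 +
              p * 7907 + s * 131) %% 2147483647)
}

#' Simulate a hypnogram for one period
#'
#' Alternating wake/NREM/REM bouts with exponential dwell times; NREM and
#' REM bouts are at least 60 s by construction (dwell = 60 s + exponential
#' excess); everything is quantised to 10 s epochs. A state with zero mean
#' dwell never occurs.
#'
#' @param config a [synth_config()]; @param period `"pre"`/`"post"`;
#' @param day day index (seeds the stream).
#' @export
simulate_hypnogram <- function(config, period = "pre", day = 1L) {
  dur <- config$period_s[[period]]
  if (dur %% 10 != 0) stop("period duration must be a multiple of 10 s")
  set.seed(derive_seed(config$seed, day, period, "hyp"))
  dw <- config$state_dwell
  n_epochs <- dur / 10
  labels <- character(0)
  state <- if (dw["wake"] > 0) "wake" else "NREM"
  while (length(labels) < n_epochs) {
    d <- if (state == "wake") {
      stats::rexp(1, 1 / max(dw["wake"], 1e-9))
    } else {
      60 + stats::rexp(1, 1 / max(dw[state] - 60, 1e-9))
    }
    k <- max(if (state == "wake") 1L else 6L, round(d / 10))
    labels <- c(labels, rep(state, k))
    state <- next_state(state, dw)
  }
  hypnogram(labels[seq_len(n_epochs)], period)
}

next_state <- function(state, dw) {
  if (state == "wake") {
    if (dw["NREM"] > 0) "NREM" else if (dw["REM"] > 0) "REM" else "wake"
  } else if (state == "NREM") {
    if (dw["REM"] > 0 && stats::runif(1) < 0.5) "REM"
    else if (dw["wake"] > 0) "wake" else "NREM"
  } else {
    if (dw["wake"] > 0) "wake" else if (dw["NREM"] > 0) "NREM" else "REM"
  }
}

## 1/f^alpha ("pink") noise via FFT spectral shaping, unit variance
pink_noise <- function(n, fs, alpha = 1.5, f_floor = 0.5) {
  nf <- n %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / n
  g <- pmax(f, f_floor)^(-alpha / 2)
  g[1] <- 0
  ph <- stats::runif(nf, 0, 2 * pi)
  X <- g * exp(1i * ph)
  full <- c(X, Conj(rev(X[2:(n - nf + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

## band-limited Gaussian noise, unit variance
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n + 2 * fs)
  y <- if (band[2] >= fs / 2 * 0.95) {
    filtfilt_zero_phase(butter_design(2, band[1], fs, "high"), x)
  } else {
    filtfilt_zero_phase(butter_design(2, band, fs, "band"), x)
  }
  y <- y[(fs + 1):(fs + n)]
  y / stats::sd(y)
}

## planted event-time placement: uniform in NREM bouts with margins,
## enforcing a minimum separation (and optionally a keep-out radius
## around existing events)
place_events <- function(n, iv, margin, min_sep, max_tries = 5000,
                         avoid = numeric(0), avoid_radius = 0) {
  if (n <= 0) return(numeric(0))
  ok_iv <- iv[iv[, 2] - iv[, 1] > 2 * margin, , drop = FALSE]
  if (!nrow(ok_iv)) return(numeric(0))
  w <- ok_iv[, 2] - ok_iv[, 1] - 2 * margin
  out <- numeric(0); tries <- 0
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1
    i <- sample.int(nrow(ok_iv), 1, prob = w)
    t0 <- stats::runif(1, ok_iv[i, 1] + margin, ok_iv[i, 2] - margin)
    if (length(out) && min(abs(out - t0)) < min_sep) next
    if (length(avoid) && min(abs(avoid - t0)) < avoid_radius) next
    out <- c(out, t0)
  }
  if (length(out) < n)
    stop("rhythm rate too high: cannot place ", n,
         " events without overlap")
  sort(out)
}

#' Simulate one period's LFP with planted rhythms and coherence
#'
#' @param hyp hypnogram of the period (from [simulate_hypnogram()]).
#' @param config a [synth_config()]; @param day day index;
#' @param period period label (selects the coherence SNR column).
#' @return list: `lfp` (channels x samples; M1 channels first),
#'   `channel_region`, `events` (list of `spindle`, `so`, `delta` planted
#'   times), `snr` used.
#' @export
simulate_lfp <- function(hyp, config, day = 1L, period = "pre") {
  fs <- config$sampling_rate
  dur <- length(hyp$labels) * hyp$epoch_s
  n <- round(dur * fs)
  set.seed(derive_seed(config$seed, day, period, "lfp"))
  n_ch <- config$n_m1_channels + config$n_dls_channels
  region <- rep(c("M1", "DLS"), c(config$n_m1_channels,
                                  config$n_dls_channels))
  ## per-sample state gains from the hypnogram
  epoch_of <- pmin(floor(seq_len(n) / (hyp$epoch_s * fs) - 1e-12) + 1,
                   length(hyp$labels))
  st <- hyp$labels[epoch_of]
  ## delta-dominated NREM, theta-dominated REM, 1/f-dominated quiet wake
  g_delta <- c(wake = 0.6, NREM = 2.0, REM = 0.3)[st]
  g_theta <- c(wake = 0.15, NREM = 0.8, REM = 2.0)[st]
  g_broad <- c(wake = 1.2, NREM = 0.5, REM = 0.3)[st]
  lfp <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    lfp[ch, ] <- g_delta * band_noise(n, fs, c(0.5, 4)) +
                 g_theta * band_noise(n, fs, c(5, 10)) +
                 g_broad * pink_noise(n, fs)
  }
  iv <- state_intervals(hyp, "NREM")
  t <- (seq_len(n) - 1) / fs
  nrem_sel <- in_intervals(t, iv)
  ## common 4-8 Hz component during NREM -> planted coherence snr/(1+snr)
  snr <- config$coherence_snr[day, period]
  if (is.na(snr)) snr <- 0
  if (snr > 0 && any(nrem_sel)) {
    gate <- gaussian_smooth(as.numeric(nrem_sel), 0.25 * fs)
    common <- band_noise(n, fs, c(4, 8)) * gate
    for (ch in seq_len(n_ch)) {
      sd48 <- stats::sd(fir_bandpass(lfp[ch, ], c(4, 8), fs)[nrem_sel])
      lfp[ch, ] <- lfp[ch, ] + sqrt(snr) * sd48 * common
    }
  }
  ## plant rhythms on every M1 channel (they live on the mean M1 signal)
  m1 <- which(region == "M1")
  mean_m1 <- colMeans(lfp[m1, , drop = FALSE])
  rates <- config$rhythm_rates
  nrem_min <- interval_duration(iv) / 60
  events <- list(spindle = numeric(0), so = numeric(0), delta = numeric(0))
  if (nrow(iv)) {
    ## SO / delta first: single biphasic cycles against the low-frequency
    ## floor (SO: tall peak + deep trough; delta: flat peak + deep trough)
    lf_sd <- stats::sd(filtfilt_zero_phase(
      butter_design(5, 4, fs, "low"), mean_m1)[nrem_sel])
    n_so <- stats::rpois(1, rates["SO"] * nrem_min)
    n_de <- stats::rpois(1, rates["delta"] * nrem_min)
    ev <- place_events(n_so + n_de, iv, margin = 2.5, min_sep = 3)
    if (length(ev)) {
      pick <- sample(c(rep("so", n_so), rep("delta", n_de)))
      for (i in seq_along(ev)) {
        if (pick[i] == "so") {
          w <- biphasic_wave(t, ev[i], config$so_span_s,
                             peak = 5 * lf_sd, trough = 5 * lf_sd)
          events$so <- c(events$so, ev[i])
        } else {
          w <- biphasic_wave(t, ev[i], config$delta_span_s,
                             peak = 0.3 * lf_sd, trough = 4 * lf_sd)
          events$delta <- c(events$delta, ev[i])
        }
        for (ch in m1) lfp[ch, w$idx] <- lfp[ch, w$idx] + w$wave
      }
    }
    ## spindles: flat-top sinusoidal bursts; amplitude = envelope mean +
    ## k s.d. of the background mean-M1 spindle-band Hilbert envelope
    ## (unsmoothed -- detector smoothing is an implementation detail), so
    ## the 2.5 / 1.5 s.d. detector thresholds are directly testable
    env <- Mod(hilbert_analytic(
      filtfilt_zero_phase(butter_design(3, c(10, 16), fs, "band"),
                          mean_m1)))[nrem_sel]
    n_sp <- stats::rpois(1, rates["spindle"] * nrem_min)
    ## "k s.d." is defined against the realized NREM envelope, which the
    ## planted events themselves inflate: solve the fixed point
    mu0 <- mean(env); v0 <- stats::var(env)
    occ <- min(0.5, n_sp * (config$spindle_dur_s + 0.1) / (60 * nrem_min))
    amp <- mu0 + config$spindle_amp_sd * sqrt(v0)
    for (it in 1:20) {
      m_mix <- (1 - occ) * mu0 + occ * amp
      v_mix <- (1 - occ) * (v0 + (mu0 - m_mix)^2) + occ * (amp - m_mix)^2
      amp <- m_mix + config$spindle_amp_sd * sqrt(v_mix)
    }
    n_nested <- min(round(config$nested_fraction * n_sp),
                    length(events$so))
    nested <- if (n_nested > 0)
      sample(events$so, n_nested) + stats::runif(n_nested, 0.3, 0.8)
    else numeric(0)
    free <- place_events(n_sp - n_nested, iv, margin = 2, min_sep = 3,
                         avoid = events$so, avoid_radius = 6)
    sp <- sort(c(nested, free))
    for (t0 in sp) {
      w <- spindle_wave(t, t0, config$spindle_freq, config$spindle_dur_s,
                        amp)
      for (ch in m1) lfp[ch, w$idx] <- lfp[ch, w$idx] + w$wave
    }
    events$spindle <- sp
    events$spindle_nested <- sort(nested)
  }
  list(lfp = lfp, channel_region = region, events = events, snr = snr)
}

## flat-top sinusoidal burst centred at t0 (the planted spindle):
## constant amplitude over `dur` with 20 ms cosine ramps, so the
## supra-threshold run of the detector envelope tracks `dur`
spindle_wave <- function(t, t0, freq, dur, amp, ramp = 0.02) {
  half <- dur / 2 + ramp
  idx <- which(t >= t0 - half & t <= t0 + half)
  tt <- t[idx] - t0
  envl <- rep(1, length(tt))
  outer_part <- abs(tt) > dur / 2
  envl[outer_part] <- 0.5 * (1 + cos(pi * (abs(tt[outer_part]) - dur / 2) /
                                     ramp))
  list(idx = idx, wave = amp * envl * cos(2 * pi * freq * tt))
}

## positive lobe then negative lobe; down-crossing at t0, total span
## `span`; corners softened by a short Gaussian so no spindle-band energy
## leaks from the derivative kinks
biphasic_wave <- function(t, t0, span, peak, trough) {
  d <- span / 2
  idx <- which(t >= t0 - d - 0.15 & t <= t0 + d + 0.15)
  tt <- t[idx] - t0
  wave <- numeric(length(tt))
  core <- abs(tt) <= d
  wave[core] <- ifelse(tt[core] < 0, peak * sin(pi * (tt[core] + d) / d),
                       -trough * sin(pi * tt[core] / d))
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  list(idx = idx, wave = gaussian_smooth(wave, 0.02 / dt))
}

#' Simulate spike trains for one period
#'
#' M1 units are inhomogeneous Poisson: base rate times a multiplicative
#' gain inside spindles and a von Mises gain on the 4-8 Hz phase of the
#' mean M1 LFP. Each coupled DLS unit receives, for each M1 spike, an
#' extra spike at `lag_s` (+ <= 2 ms Gaussian jitter) with the planted
#' excess probability (optionally boosted during spindles and after
#' SO-nested spindles), superposed on its own Poisson background.
#'
#' @param config a [synth_config()]; @param sim result of
#'   [simulate_lfp()]; @param hyp the period hypnogram.
#' @param day day index; @param period period label.
#' @param t_offset recording-time offset of the period start (s).
#' @param nested_peaks spindle peaks classed SO-nested (for the planted
#'   post-spindle boost; default: spindles within 1 s of a planted SO).
#' @return list: `units` (list of [unit()]), `truth` (coupling table).
#' @export
simulate_spike_trains <- function(config, sim, hyp, day = 1L,
                                  period = "pre", t_offset = 0,
                                  nested_peaks = NULL) {
  fs <- config$sampling_rate
  dur <- length(hyp$labels) * hyp$epoch_s
  set.seed(derive_seed(config$seed, day, period, "spk"))
  m1_rates <- rep_len(config$m1_rate, config$n_m1_units)
  dls_rates <- rep_len(config$dls_rate, config$n_dls_units)
  sp <- sim$events$spindle
  spindle_iv <- if (length(sp))
    interval_union(cbind(sp - config$spindle_dur_s / 2,
                         sp + config$spindle_dur_s / 2))
  else matrix(numeric(0), 0, 2)
  kappa <- config$phase_kappa
  phase <- NULL
  if (kappa > 0) {
    m1_mean <- colMeans(sim$lfp[sim$channel_region == "M1", , drop = FALSE])
    phase <- bandpass_phase(m1_mean, c(4, 8), fs)
  }
  gain_at <- function(tt) {
    g <- rep(1, length(tt))
    if (nrow(spindle_iv) && config$spindle_mod_depth != 1)
      g[in_intervals(tt, spindle_iv)] <- config$spindle_mod_depth
    if (!is.null(phase)) {
      ph <- phase[pmin(pmax(round(tt * fs) + 1, 1), length(phase))]
      g <- g * exp(kappa * cos(ph)) / besselI(kappa, 0)
    }
    g
  }
  m1_units <- vector("list", config$n_m1_units)
  for (i in seq_len(config$n_m1_units)) {
    rmax <- m1_rates[i] * max(config$spindle_mod_depth, 1) *
      (if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1)
    cand <- sort(stats::runif(stats::rpois(1, rmax * dur), 0, dur))
    keep <- stats::runif(length(cand)) <
      m1_rates[i] * gain_at(cand) / rmax
    m1_units[[i]] <- unit(sprintf("M1_%02d", i), "M1",
                          t_offset + cand[keep])
  }
  ## planted post-spindle coupling-boost windows (SO-nested spindles)
  if (is.null(nested_peaks)) nested_peaks <- sim$events$spindle_nested
  boost_iv <- if (config$nested_boost_prob > 0 && length(nested_peaks))
    interval_union(cbind(nested_peaks + 1, nested_peaks + 31))
  else matrix(numeric(0), 0, 2)
  dls_units <- vector("list", config$n_dls_units)
  truth <- config$coupling
  for (j in seq_len(config$n_dls_units)) {
    bg <- sort(stats::runif(stats::rpois(1, dls_rates[j] * dur), 0, dur))
    extra <- numeric(0)
    rows <- which(truth$dls == j)
    for (r in rows) {
      src <- m1_units[[truth$m1[r]]]$spike_times - t_offset
      p <- rep(truth$excess_prob[r], length(src))
      if (nrow(spindle_iv) && config$spindle_coupling_gain != 1)
        p[in_intervals(src, spindle_iv)] <-
          p[in_intervals(src, spindle_iv)] * config$spindle_coupling_gain
      if (nrow(boost_iv))
        p[in_intervals(src, boost_iv)] <-
          p[in_intervals(src, boost_iv)] + config$nested_boost_prob
      p <- pmin(p, 1)
      sel <- stats::runif(length(src)) < p
      if (any(sel))
        extra <- c(extra, src[sel] + truth$lag_s[r] +
                   stats::rnorm(sum(sel), 0, 0.001))
    }
    all_t <- sort(c(bg, extra))
    all_t <- all_t[all_t >= 0 & all_t < dur]
    all_t <- all_t[c(TRUE, diff(all_t) > 1e-5)]   # enforce distinct times
    dls_units[[j]] <- unit(sprintf("DLS_%02d", j), "DLS", t_offset + all_t)
  }
  list(units = c(m1_units, dls_units), truth = truth)
}

#' Simulate reach kinematics for all days
#'
#' Each day's mean velocity profile is a convex blend between a fixed
#' smooth noise profile and the learned template; the blend weight starts
#' at `conv_start` and grows by `conv_rate` per day, but is frozen on AP5
#' days. Trials add smooth velocity noise; positions are integrated and
#' pellet touch sits at the profile centre.
#'
#' @param config a [synth_config()].
#' @return list: `days` (list over days of lists of trials with `x`, `y`,
#'   `frame_rate`, `touch_frame`, `success`, `infusion`), `truth`
#'   (per-day blend weight and infusion label).
#' @export
simulate_reach_days <- function(config) {
  if (config$n_days < 2) stop("need n_days >= 2")
  if (config$n_trials <= 0) stop("non-positive trial count")
  set.seed(derive_seed(config$seed, 0L, "behavior", "beh"))
  fr <- config$frame_rate
  n_f <- round(1.2 * fr)             # frames per trial (1.2 s capture)
  tt <- seq_len(n_f) / fr
  template <- list(vx = 8 * exp(-((tt - 0.6) / 0.12)^2),
                   vy = 5 * (tt - 0.6) * exp(-((tt - 0.6) / 0.15)^2) * 10)
  smooth_noise <- function() {
    v <- stats::rnorm(n_f)
    k <- stats::dnorm(seq(-10, 10), sd = 3); k <- k / sum(k)
    as.numeric(stats::filter(c(rev(v[1:21]), v, rev(v[(n_f - 20):n_f])),
                             k, sides = 2))[22:(21 + n_f)]
  }
  noise_prof <- list(vx = 4 * smooth_noise(), vy = 4 * smooth_noise())
  w <- numeric(config$n_days)
  w[1] <- config$conv_start
  for (d in 2:config$n_days) {
    w[d] <- if (d %in% config$ap5_days) w[d - 1]
            else min(1, w[d - 1] + config$conv_rate)
  }
  days <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    amp <- 1 + config$peak_velocity_trend * (d - 1)
    mvx <- amp * ((1 - w[d]) * noise_prof$vx + w[d] * template$vx)
    mvy <- amp * ((1 - w[d]) * noise_prof$vy + w[d] * template$vy)
    trials <- vector("list", config$n_trials)
    for (ti in seq_len(config$n_trials)) {
      vx <- mvx + config$trial_noise_sd * smooth_noise()
      vy <- mvy + config$trial_noise_sd * smooth_noise()
      trials[[ti]] <- list(x = cumsum(vx) / fr, y = cumsum(vy) / fr,
                           frame_rate = fr,
                           touch_frame = round(n_f / 2),
                           success = TRUE,
                           infusion = if (d %in% config$ap5_days) "AP5"
                                      else "saline")
    }
    days[[d]] <- trials
  }
  list(days = days,
       truth = data.frame(day = seq_len(config$n_days), blend = w,
                          infusion = ifelse(seq_len(config$n_days) %in%
                                            config$ap5_days,
                                            "AP5", "saline")))
}

#' Simulate one full session (one day)
#'
#' Assembles pre / train / post periods: planted hypnograms and rhythm
#' LFP in pre and post, broadband wake LFP during training with reach
#' trials, spike trains throughout, and movement flags consistent with the
#' planted states.
#'
#' @param config a [synth_config()]; @param day day index.
#' @return list: `session` (a [session()]), `truth` (hypnograms, planted
#'   events, coupling, coherence SNR).
#' @export
simulate_session <- function(config, day = 1L) {
  fs <- config$sampling_rate
  durs <- config$period_s
  starts <- cumsum(c(0, durs))[1:3]
  names(starts) <- names(durs)
  truth <- list(day = day, coupling = config$coupling,
                snr = config$coherence_snr[day, ])
  lfp_parts <- list(); units_acc <- NULL
  movement <- list()
  for (per in c("pre", "train", "post")) {
    if (per == "train") {
      set.seed(derive_seed(config$seed, day, "train", "lfp"))
      n <- round(durs[["train"]] * fs)
      n_ch <- config$n_m1_channels + config$n_dls_channels
      m <- matrix(0, n_ch, n)
      for (ch in seq_len(n_ch))
        m[ch, ] <- band_noise(n, fs, c(0.5, min(45, fs / 2.5)))
      lfp_parts$train <- m
      movement$train <- rep(TRUE, durs[["train"]] / 10)
      next
    }
    hyp <- simulate_hypnogram(config, per, day)
    sim <- simulate_lfp(hyp, config, day, per)
    spk <- simulate_spike_trains(config, sim, hyp, day, per,
                                 t_offset = starts[[per]])
    lfp_parts[[per]] <- sim$lfp
    truth[[paste0("hyp_", per)]] <- hyp
    truth[[paste0("events_", per)]] <- sim$events
    units_acc <- merge_period_units(units_acc, spk$units)
    set.seed(derive_seed(config$seed, day, per, "mov"))
    movement[[per]] <- ifelse(hyp$labels == "wake",
                              stats::runif(length(hyp$labels)) < 0.8,
                              FALSE)
    truth$channel_region <- sim$channel_region
  }
  ## task-modulated spiking during training: rate bump around each touch
  set.seed(derive_seed(config$seed, day, "train", "spk"))
  touch <- starts[["train"]] +
    seq(10, durs[["train"]] - 10, length.out = config$n_trials)
  train_units <- simulate_train_spikes(config, durs[["train"]],
                                       starts[["train"]], touch)
  units_acc <- merge_period_units(units_acc, train_units)
  lfp <- do.call(cbind, lfp_parts[c("pre", "train", "post")])
  trials <- data.frame(trial_id = sprintf("t%03d", seq_along(touch)),
                       touch_time_s = touch)
  s <- session(sprintf("synth_d%02d", day), fs, lfp, truth$channel_region,
               units_acc,
               periods = list(pre = c(0, starts[["train"]]),
                              train = c(starts[["train"]],
                                        starts[["post"]]),
                              post = c(starts[["post"]],
                                       starts[["post"]] + durs[["post"]])),
               movement = movement, trials = trials, day_index = day)
  list(session = s, truth = truth)
}

## homogeneous background + Gaussian peri-touch rate bump
simulate_train_spikes <- function(config, dur, t0, touch) {
  mk <- function(id, region, base) {
    cand <- sort(stats::runif(stats::rpois(1, base * 2 * dur), 0, dur)) + t0
    rel <- vapply(cand, function(tt) min(abs(tt - touch)), 0)
    gain <- 0.5 + 1.5 * exp(-rel^2 / (2 * 0.3^2))
    unit(id, region, cand[stats::runif(length(cand)) < gain / 2])
  }
  c(lapply(seq_len(config$n_m1_units), function(i)
      mk(sprintf("M1_%02d", i), "M1", rep_len(config$m1_rate,
                                              config$n_m1_units)[i])),
    lapply(seq_len(config$n_dls_units), function(j)
      mk(sprintf("DLS_%02d", j), "DLS", rep_len(config$dls_rate,
                                                config$n_dls_units)[j])))
}

## concatenate per-period spike times of identically named units
merge_period_units <- function(acc, add) {
  if (is.null(acc)) return(add)
  ids <- vapply(acc, function(u) u$unit_id, "")
  for (u in add) {
    k <- match(u$unit_id, ids)
    if (is.na(k)) {
      acc[[length(acc) + 1]] <- u
      ids <- c(ids, u$unit_id)
    } else {
      st <- sort(c(acc[[k]]$spike_times, u$spike_times))
      acc[[k]]$spike_times <- st[c(TRUE, diff(st) > 1e-9)]
    }
  }
  acc
}
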