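## NREM rhythm detection and spiking modulation.
##
## Spindles: 10-16 Hz zero-phase 3rd-order Butterworth, Gaussian-smoothed
## Hilbert envelope, dual threshold (>= 1.5 s.d. for >= 500 ms containing a
## sample > 2.5 s.d., thresholds from the NREM envelope), events < 300 ms
## apart merged. SOs/delta waves: 0.1 Hz high-pass then 4 Hz low-pass,
## positive-to-negative zero crossings with peak/trough percentile and
## span rules.

#' Detect sleep spindles on a mean M1 LFP signal
#'
#' @param x mean LFP signal (recording time); @param fs Hz.
#' @param hyp [hypnogram()] providing NREM bouts (threshold pool and event
#'   gating).
#' @param band spindle band (default 10-16 Hz).
#' @param smooth_sd_s Gaussian envelope smoothing s.d. (default 0.040 s).
#' @param thr_peak peak threshold in s.d. units (default 2.5).
#' @param thr_dur sustained threshold in s.d. units (default 1.5).
#' @param min_dur_s minimum supra-threshold duration (default 0.5 s).
#' @param merge_gap_s events closer than this are combined (default 0.3 s).
#' @param use_power apply thresholds to the squared envelope instead
#'   (alternative reading of "power"; default FALSE).
#' @return data.frame: `start_s`, `end_s`, `peak_s`, `peak_envelope`
#'   (s.d. units).
#' @export
detect_spindles <- function(x, fs, hyp, band = c(10, 16),
                            smooth_sd_s = 0.040, thr_peak = 2.5,
                            thr_dur = 1.5, min_dur_s = 0.5,
                            merge_gap_s = 0.3, use_power = FALSE) {
  iv <- state_intervals(hyp, "NREM")
  if (!nrow(iv)) stop("hypnogram contains no NREM")
  xf <- filtfilt_zero_phase(butter_design(3, band, fs, "band"), x)
  env <- gaussian_smooth(Mod(hilbert_analytic(xf)), smooth_sd_s * fs)
  if (use_power) env <- env^2
  t <- (seq_along(x) - 1) / fs
  nrem <- in_intervals(t, iv)
  mu <- mean(env[nrem]); sdv <- stats::sd(env[nrem])
  lo <- mu + thr_dur * sdv
  hi <- mu + thr_peak * sdv
  r <- rle(env > lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= min_dur_s * fs)
  ev <- list()
  for (ci in cand) {
    sl <- starts[ci]:ends[ci]
    if (!any(env[sl] > hi)) next
    ev[[length(ev) + 1]] <- c(t[starts[ci]], t[ends[ci]])
  }
  if (!length(ev)) return(spindle_frame())
  ev <- do.call(rbind, ev)
  ev <- merge_events(ev, merge_gap_s)
  out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    sl <- which(t >= ev[i, 1] & t <= ev[i, 2])
    pk <- sl[which.max(env[sl])]
    data.frame(start_s = ev[i, 1], end_s = ev[i, 2], peak_s = t[pk],
               peak_envelope = (env[pk] - mu) / sdv)
  }))
  out[in_intervals(out$peak_s, iv), , drop = FALSE]
}

spindle_frame <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), peak_s = numeric(0),
             peak_envelope = numeric(0))
}

## combine events whose gap is below `gap_s`; order-independent, idempotent
merge_events <- function(ev, gap_s) {
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev[i, 1] - out[nrow(out), 2] < gap_s) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], ev[i, 2])
    } else out <- rbind(out, ev[i, , drop = FALSE])
  }
  out
}

#' Detect slow oscillations and delta waves
#'
#' The mean LFP is filtered (2nd-order 0.1 Hz high-pass, then 5th-order
#' 4 Hz low-pass, both zero-phase Butterworth). Every positive-to-negative
#' zero crossing in NREM yields a candidate with its previous peak,
#' following trough and surrounding negative-to-positive crossings (span =
#' time between the latter). Percentile pools are all candidates of the
#' period. SO: peak in the top 15% of peaks, trough in the top (deepest)
#' 40% of troughs, 0.3 s < span <= 1 s. Delta: peak in the bottom 85%,
#' trough in the top 40%, span > 0.25 s. SO takes precedence; classes are
#' disjoint.
#'
#' @inheritParams detect_spindles
#' @return list with data.frames `so` and `delta`, each with
#'   `down_cross_s`, `peak_s`, `peak_amp`, `trough_s`, `trough_amp`,
#'   `span_s`, `upstate_peak_s`; and `candidates` (all scored candidates
#'   with their `class`).
#' @export
detect_so_delta <- function(x, fs, hyp) {
  iv <- state_intervals(hyp, "NREM")
  if (!nrow(iv)) stop("hypnogram contains no NREM")
  xf <- filtfilt_zero_phase(butter_design(2, 0.1, fs, "high"), x)
  xf <- filtfilt_zero_phase(butter_design(5, 4, fs, "low"), xf)
  t <- (seq_along(x) - 1) / fs
  sgn <- sign(xf)
  dn <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)   # pos-to-neg
  up <- which(sgn[-length(sgn)] <= 0 & sgn[-1] > 0)   # neg-to-pos
  dn <- dn[in_intervals(t[dn], iv)]
  cands <- list()
  for (d in dn) {
    prev_up <- up[up < d]
    next_up <- up[up > d]
    if (!length(prev_up) || !length(next_up)) next
    u0 <- max(prev_up); u1 <- min(next_up)
    pk <- (u0:d)[which.max(xf[u0:d])]
    tr <- (d:u1)[which.min(xf[d:u1])]
    cands[[length(cands) + 1]] <-
      data.frame(down_cross_s = t[d], peak_s = t[pk], peak_amp = xf[pk],
                 trough_s = t[tr], trough_amp = xf[tr],
                 span_s = t[u1] - t[u0], upstate_peak_s = t[pk])
  }
  if (!length(cands)) stop("no SO/delta candidates in NREM")
  cd <- classify_so_delta_candidates(do.call(rbind, cands))
  list(so = cd[cd$class == "SO", , drop = FALSE],
       delta = cd[cd$class == "delta", , drop = FALSE],
       candidates = cd)
}

#' Apply the SO/delta classification rules to a candidate table
#'
#' Percentile pools are the supplied candidates (linear-interpolation
#' quantiles). Exposed separately from the detection so the rule branches
#' can be exercised on hand-constructed candidate features.
#'
#' @param cd data.frame with `peak_amp`, `trough_amp`, `span_s` (plus any
#'   landmark columns, passed through).
#' @return `cd` with a `class` column in `"SO"`, `"delta"`, `"none"`.
#' @export
classify_so_delta_candidates <- function(cd) {
  pk_hi <- stats::quantile(cd$peak_amp, 0.85, names = FALSE)   # top 15%
  tr_hi <- stats::quantile(cd$trough_amp, 0.40, names = FALSE) # deepest 40%
  is_so <- cd$peak_amp >= pk_hi & cd$trough_amp <= tr_hi &
    cd$span_s > 0.3 & cd$span_s <= 1.0
  is_delta <- !is_so & cd$peak_amp < pk_hi & cd$trough_amp <= tr_hi &
    cd$span_s > 0.25
  cd$class <- ifelse(is_so, "SO", ifelse(is_delta, "delta", "none"))
  cd
}

#' Classify spindles by proximity to the preceding slow oscillation
#'
#' Delay is spindle peak minus the most recent preceding SO
#' positive-to-negative zero crossing. `<= 1` s: SO-nested; `>= 5` s:
#' non-SO-nested; otherwise (including no preceding SO): unclassified.
#'
#' @param spindles data.frame from [detect_spindles()].
#' @param so data.frame of SOs from [detect_so_delta()].
#' @return data.frame: `spindle_peak_s`, `delay_s`, `class`.
#' @export
classify_nesting <- function(spindles, so) {
  if (!nrow(spindles))
    return(data.frame(spindle_peak_s = numeric(0), delay_s = numeric(0),
                      class = character(0)))
  zc <- sort(so$down_cross_s)
  delay <- vapply(spindles$peak_s, function(p) {
    prev <- zc[zc <= p]
    if (!length(prev)) NA_real_ else p - max(prev)
  }, 0)
  cls <- ifelse(is.na(delay), "unclassified",
         ifelse(delay <= 1, "SO-nested",
         ifelse(delay >= 5, "non-SO-nested", "unclassified")))
  data.frame(spindle_peak_s = spindles$peak_s, delay_s = delay, class = cls)
}

#' Peri-event time histogram of one unit around event landmarks
#'
#' 10 ms bins spanning -2 s to +2 s (400 bins), averaged across events;
#' returned as firing rate in Hz.
#'
#' @param spike_times seconds; @param event_times landmark times.
#' @param window `c(lo, hi)` seconds (default -2..2); @param bin_s bin
#'   width (default 0.010).
#' @return list with `bin_centers` and `rate` (Hz).
#' @export
event_peth <- function(spike_times, event_times, window = c(-2, 2),
                       bin_s = 0.010) {
  edges <- seq(window[1], window[2], by = bin_s)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (ev in event_times) {
    rel <- spike_times - ev
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      counts <- counts + tabulate(floor((rel - window[1]) / bin_s) + 1, nb)
  }
  list(bin_centers = edges[-1] - bin_s / 2,
       rate = counts / (length(event_times) * bin_s))
}

#' Rhythm modulation of a unit's firing
#'
#' Modulation is the min-to-max firing-rate range of the event-locked PETH
#' in the second around the landmark (-0.5..0.5 s) divided by the range in
#' the preceding baseline second (-1.5..-0.5 s).
#'
#' @inheritParams event_peth
#' @param min_events minimum number of events (default 10).
#' @return list: `peth`, `modulation` (`NA` + `undefined = TRUE` when the
#'   baseline range is zero), `n_events`.
#' @export
unit_event_modulation <- function(spike_times, event_times,
                                  min_events = 10) {
  if (length(event_times) < min_events)
    stop("need at least ", min_events, " events")
  p <- event_peth(spike_times, event_times)
  m <- peth_modulation(p$rate, p$bin_centers)
  list(peth = p, modulation = m, undefined = is.na(m),
       n_events = length(event_times))
}

peth_modulation <- function(rate, centers) {
  ev <- rate[centers > -0.5 & centers < 0.5]
  bl <- rate[centers > -1.5 & centers < -0.5]
  rng <- function(v) max(v) - min(v)
  if (rng(bl) == 0) return(NA_real_)
  rng(ev) / rng(bl)
}

#' Shuffle test for rhythm modulation
#'
#' The PETH's time bins are permuted and the modulation recomputed
#' `n_shuffle` times; a unit is significantly modulated when the real
#' modulation exceeds the 99th percentile of the shuffled distribution.
#'
#' @param mod result of [unit_event_modulation()].
#' @param n_shuffle number of shuffles (default 1000).
#' @param seed RNG seed for reproducibility (optional).
#' @return list: `significant`, `shuffle_q99`, `shuffle_modulations`.
#' @export
modulation_significance <- function(mod, n_shuffle = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- mod$peth$rate
  centers <- mod$peth$bin_centers
  sh <- vapply(seq_len(n_shuffle), function(i)
    peth_modulation(sample(rate), centers), 0)
  sh[is.na(sh)] <- 0
  q99 <- stats::quantile(sh, 0.99, names = FALSE)
  list(significant = !is.na(mod$modulation) && mod$modulation > q99,
       shuffle_q99 = q99, shuffle_modulations = sh)
}
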