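## Short-latency M1 -> DLS spike coupling by the interval-jitter method.
##
## Spiking is binned at 1 ms and concatenated across analysis intervals
## with a guard gap so no cross-boundary lags are counted. The coupling
## statistic is the mean cross-correlogram value over 1-15 ms lags
## (positive lag = DLS after M1), expressed per M1 reference spike so it is
## comparable across conditions with different rates. Surrogates jitter
## each DLS spike uniformly within a 50 ms window centred on the spike
## (clipped to its interval); a pair is coupled when the real statistic
## exceeds the 99th percentile of 1000 surrogate statistics.

SHORT_LAGS <- 1:15   # ms, the monosynaptic-latency window

## bin spike times into concatenated 1 ms bins over disjoint intervals;
## returns bins plus per-spike interval bounds (for jitter clipping)
concat_bins <- function(spike_times, intervals, guard_bins = 256L) {
  iv <- as_intervals(intervals)
  if (!nrow(iv)) stop("no analysis intervals")
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  nb <- floor((iv[, 2] - iv[, 1]) * 1000)
  off <- cumsum(c(0, (nb + guard_bins)[-length(nb)]))
  bins <- integer(0); lo <- integer(0); hi <- integer(0)
  for (i in seq_len(nrow(iv))) {
    sel <- spike_times >= iv[i, 1] & spike_times < iv[i, 2]
    if (!any(sel)) next
    b <- floor((spike_times[sel] - iv[i, 1]) * 1000)
    b <- pmin(b, nb[i] - 1L)
    bins <- c(bins, off[i] + b)
    lo <- c(lo, rep(off[i], sum(sel)))
    hi <- c(hi, rep(off[i] + nb[i] - 1L, sum(sel)))
  }
  o <- order(bins)
  list(bins = bins[o], int_lo = lo[o], int_hi = hi[o],
       duration_s = sum(nb) / 1000)
}

#' Cross-correlogram of an M1/DLS unit pair
#'
#' Counts of DLS-minus-M1 spike-bin differences per 1 ms lag over
#' concatenated intervals; positive lags mean DLS fires after M1.
#'
#' @param m1_times,dls_times spike times in seconds.
#' @param intervals half-open analysis intervals (matrix or vector).
#' @param max_lag_ms largest lag magnitude (default 100).
#' @return list of class `cs_ccg`: `lags_ms`, `counts`, `n_m1`, `n_dls`,
#'   `duration_s`.
#' @export
cross_correlogram <- function(m1_times, dls_times, intervals,
                              max_lag_ms = 100L) {
  cm <- concat_bins(m1_times, intervals)
  cd <- concat_bins(dls_times, intervals)
  if (!length(cm$bins) || !length(cd$bins)) stop("a unit has no spikes in intervals")
  counts <- ccg_counts_binned(cm$bins, cd$bins, max_lag_ms)
  structure(list(lags_ms = -max_lag_ms:max_lag_ms, counts = counts,
                 n_m1 = length(cm$bins), n_dls = length(cd$bins),
                 duration_s = cm$duration_s),
            class = "cs_ccg")
}

## pairwise lag histogram between two sorted integer bin vectors
ccg_counts_binned <- function(m1b, dlsb, max_lag) {
  lo <- findInterval(dlsb - max_lag - 0.5, m1b) + 1L
  hi <- findInterval(dlsb + max_lag + 0.5, m1b)
  n <- hi - lo + 1L
  keep <- n > 0L
  if (!any(keep)) return(integer(2L * max_lag + 1L))
  idx <- sequence(n[keep], from = lo[keep])
  lags <- rep(dlsb[keep], n[keep]) - m1b[idx]
  tabulate(lags + max_lag + 1L, 2L * max_lag + 1L)
}

## mean over the short-latency lags, per M1 reference spike
short_latency_stat <- function(counts, lags_ms, n_m1) {
  mean(counts[lags_ms %in% SHORT_LAGS]) / n_m1
}

#' Interval-jitter surrogate ensemble for one pair
#'
#' Each surrogate redraws every DLS spike uniformly within a 50 ms window
#' centred on the spike (clipped to its interval), destroying sub-50 ms
#' spike-timing structure while preserving slower co-modulation. Returns
#' the per-surrogate short-latency statistics (Monte Carlo) and the exact
#' expected surrogate CCG (the analytic limit of averaging jittered CCGs,
#' computed by smearing each DLS spike over its allowed jitter positions).
#'
#' @inheritParams cross_correlogram
#' @param n_surrogates ensemble size (default 1000; < 100 warns).
#' @param window_ms jitter window width (default 50).
#' @param seed RNG seed (optional).
#' @param mc draw the Monte Carlo ensemble (default TRUE); FALSE returns
#'   only the exact expected surrogate CCG.
#' @return list: `surrogate_stats` (length `n_surrogates`), `mean_ccg`
#'   (expected surrogate counts per lag), `lags_ms`, `q99` of the
#'   surrogate statistics.
#' @export
jitter_surrogates <- function(m1_times, dls_times, intervals,
                              n_surrogates = 1000L, window_ms = 50L,
                              max_lag_ms = 100L, seed = NULL, mc = TRUE) {
  if (mc && n_surrogates < 100L)
    warning("fewer than 100 surrogates: percentile unstable")
  if (!is.null(seed)) set.seed(seed)
  cm <- concat_bins(m1_times, intervals)
  cd <- concat_bins(dls_times, intervals)
  m1b <- cm$bins
  half <- window_ms %/% 2L
  u_lo <- pmax(cd$bins - half, cd$int_lo) - cd$bins        # offset bounds
  u_hi <- pmin(cd$bins + half - 1L, cd$int_hi) - cd$bins
  w <- u_hi - u_lo + 1L
  nd <- length(cd$bins)
  lags <- -max_lag_ms:max_lag_ms

  ## exact expected surrogate CCG by smearing each DLS spike over its
  ## allowed offsets with weight 1/w (difference-array accumulation)
  L <- max_lag_ms + half + 1L
  lo_i <- findInterval(cd$bins - L - 0.5, m1b) + 1L
  hi_i <- findInterval(cd$bins + L + 0.5, m1b)
  n <- hi_i - lo_i + 1L
  keep <- n > 0L
  acc <- numeric(2L * (max_lag_ms + window_ms) + 3L)
  offset0 <- max_lag_ms + window_ms + 1L
  if (any(keep)) {
    idx <- sequence(n[keep], from = lo_i[keep])
    j <- rep(which(keep), n[keep])
    lam <- rep(cd$bins[keep], n[keep]) - m1b[idx]
    wts <- 1 / w[j]
    a_lo <- lam + u_lo[j] + offset0
    a_hi <- lam + u_hi[j] + 1L + offset0
    ok <- a_lo >= 1 & a_lo <= length(acc)
    for (tab in list(cbind(a_lo[ok], wts[ok]),
                     cbind(pmin(a_hi[ok], length(acc)), -wts[ok]))) {
      s <- rowsum(tab[, 2], tab[, 1])
      acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s
    }
  }
  mean_ccg <- cumsum(acc)[lags + offset0]

  stats_out <- numeric(0)
  q99 <- NA_real_
  if (mc && n_surrogates > 0L) {
    ## Monte Carlo short-latency statistics: N[j, u] = number of M1 spikes
    ## at short lags from position bins[j] + u
    u_vals <- (-half):(half - 1L)
    pos <- outer(cd$bins, u_vals, "+")
    N <- matrix(findInterval(pos - min(SHORT_LAGS) + 0.5, m1b) -
                findInterval(pos - max(SHORT_LAGS) - 0.5, m1b),
                nrow = nd)
    stats_out <- numeric(n_surrogates)
    block <- max(1L, min(n_surrogates, floor(5e6 / max(nd, 1L))))
    done <- 0L
    while (done < n_surrogates) {
      nb <- min(block, n_surrogates - done)
      u <- u_lo + floor(stats::runif(nd * nb) * w)
      vals <- N[cbind(rep(seq_len(nd), nb), u + half + 1L)]
      stats_out[(done + 1L):(done + nb)] <-
        colSums(matrix(vals, nd, nb)) / (length(SHORT_LAGS) * length(m1b))
      done <- done + nb
    }
    q99 <- stats::quantile(stats_out, 0.99, names = FALSE)
  }
  list(surrogate_stats = stats_out, mean_ccg = mean_ccg, lags_ms = lags,
       q99 = q99, n_m1 = length(m1b), n_dls = nd)
}

#' First minutes of NREM within a period
#'
#' @param hyp a [hypnogram()]; @param minutes how many NREM minutes to take
#'   (default 5).
#' @return interval matrix totalling at most `minutes` of NREM, taken in
#'   temporal order.
#' @export
first_nrem_minutes <- function(hyp, minutes = 5) {
  iv <- state_intervals(hyp, "NREM")
  budget <- minutes * 60
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(iv))) {
    if (budget <= 0) break
    d <- min(iv[i, 2] - iv[i, 1], budget)
    out <- rbind(out, c(iv[i, 1], iv[i, 1] + d))
    budget <- budget - d
  }
  out
}

#' Coupling verdict for one M1/DLS pair
#'
#' Evaluated on the first 5 NREM minutes of the pre-training period plus
#' the first 5 of the post-training period (10 min total). Coupled when the
#' real short-latency statistic exceeds the surrogate 99th percentile.
#'
#' @param m1_times,dls_times spike times (seconds).
#' @param hyp_pre,hyp_post hypnograms of the two periods.
#' @param n_surrogates,seed forwarded to [jitter_surrogates()].
#' @param minutes NREM minutes per period (default 5; periods with less
#'   are an error).
#' @return list: `coupled`, `real_stat`, `q99`, `normalized_ccg`
#'   (real counts minus expected surrogate counts, per M1 spike),
#'   `lags_ms`, `intervals`.
#' @export
detect_coupled <- function(m1_times, dls_times, hyp_pre, hyp_post,
                           n_surrogates = 1000L, seed = NULL, minutes = 5) {
  iv1 <- first_nrem_minutes(hyp_pre, minutes)
  iv2 <- first_nrem_minutes(hyp_post, minutes)
  if (interval_duration(iv1) < minutes * 60 - 1e-9 ||
      interval_duration(iv2) < minutes * 60 - 1e-9)
    stop("insufficient NREM for coupling evaluation")
  iv <- rbind(iv1, iv2)
  real <- cross_correlogram(m1_times, dls_times, iv)
  ens <- jitter_surrogates(m1_times, dls_times, iv,
                           n_surrogates = n_surrogates, seed = seed)
  stat <- short_latency_stat(real$counts, real$lags_ms, real$n_m1)
  list(coupled = stat > ens$q99,
       real_stat = stat, q99 = ens$q99,
       normalized_ccg = (real$counts - ens$mean_ccg) / real$n_m1,
       lags_ms = real$lags_ms, intervals = iv,
       n_m1 = real$n_m1, n_dls = real$n_dls)
}

#' Jitter-normalised short-latency transmission magnitude
#'
#' Mean over 1-15 ms lags of (real minus expected-surrogate) CCG counts per
#' M1 reference spike, on arbitrary condition intervals. Rate changes that
#' survive jittering cancel in the subtraction, so magnitudes are
#' comparable across behavioral states and rhythms.
#'
#' @inheritParams cross_correlogram
#' @param min_ref below this many M1 reference spikes the value is flagged
#'   low-n (default 50).
#' @return list: `magnitude`, `n_m1`, `n_dls`, `duration_s`, `low_n`.
#' @export
normalized_magnitude <- function(m1_times, dls_times, intervals,
                                 min_ref = 50L) {
  real <- cross_correlogram(m1_times, dls_times, intervals,
                            max_lag_ms = max(SHORT_LAGS))
  ens <- jitter_surrogates(m1_times, dls_times, intervals,
                           n_surrogates = 0L, max_lag_ms = max(SHORT_LAGS),
                           mc = FALSE)
  sel <- real$lags_ms %in% SHORT_LAGS
  mag <- mean(real$counts[sel] - ens$mean_ccg[sel]) / real$n_m1
  list(magnitude = mag, n_m1 = real$n_m1, n_dls = real$n_dls,
       duration_s = real$duration_s, low_n = real$n_m1 < min_ref)
}

#' Transmission magnitude by behavioral state
#'
#' NREM and wake intervals are pooled across the pre- and post-training
#' periods; the jitter-normalised magnitude is computed per state.
#'
#' @param m1_times,dls_times spike times.
#' @param hyp_pre,hyp_post period hypnograms.
#' @return list with `NREM`, `wake` ([normalized_magnitude()] results) and
#'   `difference` (NREM minus wake).
#' @export
transmission_by_state <- function(m1_times, dls_times, hyp_pre, hyp_post) {
  out <- list()
  for (st in c("NREM", "wake")) {
    iv <- rbind(state_intervals(hyp_pre, st), state_intervals(hyp_post, st))
    if (!nrow(iv)) stop("state ", st, " absent from both periods")
    out[[st]] <- normalized_magnitude(m1_times, dls_times, iv)
  }
  out$difference <- out$NREM$magnitude - out$wake$magnitude
  out
}

#' Transmission magnitude by NREM rhythm
#'
#' Condition intervals are 1 s windows centred on each rhythm landmark
#' (spindle peak; SO/delta upstate peak), pooled across events.
#'
#' @param m1_times,dls_times spike times.
#' @param events named list of landmark-time vectors (e.g. `spindle`, `SO`,
#'   `delta`).
#' @param min_events rhythms with fewer events are skipped (default 10).
#' @return named list of [normalized_magnitude()] results (skipped rhythms
#'   are absent).
#' @export
transmission_by_rhythm <- function(m1_times, dls_times, events,
                                   min_events = 10) {
  out <- list()
  for (nm in names(events)) {
    ev <- events[[nm]]
    if (length(ev) < min_events) next
    iv <- interval_union(cbind(ev - 0.5, ev + 0.5))
    out[[nm]] <- normalized_magnitude(m1_times, dls_times, iv)
  }
  out
}

#' Within-period transmission change (first vs second half)
#'
#' @param m1_times,dls_times spike times.
#' @param period `c(start, end)` seconds.
#' @param hyp hypnogram of the period.
#' @return list: `first`, `second` (magnitudes on NREM of each half) and
#'   `change` (second minus first).
#' @export
half_period_change <- function(m1_times, dls_times, period, hyp) {
  mid <- mean(period)
  halves <- list(first = c(period[1], mid), second = c(mid, period[2]))
  nrem <- state_intervals(hyp, "NREM")
  out <- list()
  for (nm in names(halves)) {
    iv <- interval_intersect(matrix(halves[[nm]], 1), nrem)
    if (!nrow(iv)) stop("NREM absent in ", nm, " half")
    out[[nm]] <- normalized_magnitude(m1_times, dls_times, iv)
  }
  out$change <- out$second$magnitude - out$first$magnitude
  out
}

PERI_SPINDLE_BINS <- rbind(c(-91, -61), c(-61, -31), c(-31, -1),
                           c(1, 30), c(31, 61), c(61, 91))

#' Transmission, firing-rate and spindle-rate dynamics around spindles
#'
#' Six 30 s bins around each spindle peak (edges as printed:
#' -91/-61/-31/-1 and 1/30/31/61/61/91 s, excluding the spindle itself).
#' For each nesting class, condition intervals pool the corresponding bin
#' across that class's spindles; every curve is baseline-subtracted by its
#' first bin. Spindles whose +/- 91 s window crosses a period edge are
#' dropped.
#'
#' @param m1_times,dls_times spike times of one coupled pair.
#' @param nesting data.frame from [classify_nesting()].
#' @param period `c(start, end)` of the period containing the spindles.
#' @return data.frame: `class`, `bin` (1-6), `bin_lo_s`, `bin_hi_s`,
#'   `transmission`, `m1_rate`, `dls_rate`, `spindle_rate` (all baseline
#'   subtracted), `n_spindles`.
#' @export
peri_spindle_transmission <- function(m1_times, dls_times, nesting,
                                      period) {
  all_peaks <- nesting$spindle_peak_s
  rows <- list()
  for (cls in c("SO-nested", "non-SO-nested")) {
    pk <- nesting$spindle_peak_s[nesting$class == cls]
    pk <- pk[pk - 91 >= period[1] & pk + 91 <= period[2]]
    if (!length(pk)) next
    vals <- matrix(NA_real_, nrow(PERI_SPINDLE_BINS), 4)
    for (b in seq_len(nrow(PERI_SPINDLE_BINS))) {
      iv <- interval_union(cbind(pk + PERI_SPINDLE_BINS[b, 1],
                                 pk + PERI_SPINDLE_BINS[b, 2]))
      dur <- interval_duration(iv)
      nm <- normalized_magnitude(m1_times, dls_times, iv, min_ref = 1L)
      vals[b, ] <- c(nm$magnitude,
                     sum(in_intervals(m1_times, iv)) / dur,
                     sum(in_intervals(dls_times, iv)) / dur,
                     sum(in_intervals(all_peaks, iv)) / dur)
    }
    vals <- sweep(vals, 2, vals[1, ])
    rows[[cls]] <- data.frame(class = cls, bin = seq_len(nrow(vals)),
                              bin_lo_s = PERI_SPINDLE_BINS[, 1],
                              bin_hi_s = PERI_SPINDLE_BINS[, 2],
                              transmission = vals[, 1],
                              m1_rate = vals[, 2], dls_rate = vals[, 3],
                              spindle_rate = vals[, 4],
                              n_spindles = length(pk))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
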