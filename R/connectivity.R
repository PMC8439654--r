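## Corticostriatal LFP functional connectivity: referencing,
## normalisation, NREM-restricted multitaper coherence across all M1 x DLS
## electrode pairs, 4-8 Hz band summaries, online/offline decomposition
## across days, and 4-8 Hz phase differences.

#' Common-median referencing within each region
#'
#' At every sample the within-region median is subtracted from each channel
#' of that region; M1 and DLS are processed independently. Reduces common
#' noise and volume conduction.
#'
#' @param lfp channels x samples matrix.
#' @param channel_region region label per channel.
#' @export
common_median_reference <- function(lfp, channel_region) {
  out <- lfp
  for (reg in unique(channel_region)) {
    sel <- channel_region == reg
    med <- apply(lfp[sel, , drop = FALSE], 2, stats::median)
    out[sel, ] <- sweep(lfp[sel, , drop = FALSE], 2, med)
  }
  out
}

#' z-score each channel over the whole recording
#' @param lfp channels x samples matrix.
#' @export
zscore_channels <- function(lfp) {
  sds <- apply(lfp, 1, stats::sd)
  if (any(sds == 0))
    stop("constant channel(s): ", paste(which(sds == 0), collapse = ","))
  sweep(sweep(lfp, 1, rowMeans(lfp)), 1, sds, "/")
}

#' Flag artifact channels by gross amplitude
#'
#' Automated stand-in for manual rejection of noisy electrodes: channels
#' whose standard deviation exceeds `factor` times the median channel s.d.
#' are flagged.
#' @param lfp channels x samples matrix; @param factor threshold multiple
#'   (default 5).
#' @return logical vector, TRUE = keep.
#' @export
artifact_channel_mask <- function(lfp, factor = 5) {
  sds <- apply(lfp, 1, stats::sd)
  sds <= factor * stats::median(sds)
}

#' NREM-restricted multitaper coherence between two LFP channels
#'
#' Coherence magnitude is computed in every non-overlapping 10 s window
#' that lies inside a NREM bout, then averaged across windows (magnitude
#' averaging; `average = "complex"` exposes the alternative).
#'
#' @param x,y two LFP signals in recording time (full-session vectors).
#' @param fs sampling rate (Hz).
#' @param hyp a [hypnogram()] restricting the windows.
#' @param nw,k multitaper parameters; @param average see [mt_coherence()].
#' @return list with `freq`, `coherence` (summary spectrum), per-window
#'   matrix `coh`, `window_start_s`, `n_windows` and `reliable`
#'   (`n_windows >= 3`).
#' @export
nrem_coherence <- function(x, y, fs, hyp, nw = 3, k = 5,
                           average = c("magnitude", "complex")) {
  average <- match.arg(average)
  iv <- state_intervals(hyp, "NREM")
  if (!nrow(iv)) stop("no NREM windows in hypnogram")
  starts <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    n <- floor((iv[i, 2] - iv[i, 1]) / 10)
    iv[i, 1] + 10 * (seq_len(n) - 1)
  }))
  r <- mt_coherence(x, y, fs, window_s = 10, nw = nw, k = k,
                    starts_s = starts, average = average)
  r$n_windows <- length(starts)
  r$reliable <- length(starts) >= 3
  r
}

#' Band-mean coherence and the high-coherence flag
#'
#' Mean coherence over the band's frequency bins (closed interval on the
#' grid) and over windows; pairs with band mean strictly above `high_thresh`
#' are flagged high-coherence.
#'
#' @param coh result of [nrem_coherence()] (or any list with `freq` and
#'   per-window `coh`).
#' @param band `c(lo, hi)` Hz, default 4-8.
#' @param high_thresh flag threshold, default 0.6.
#' @return list with `band_mean` and `high_pair`.
#' @export
coherence_band_mean <- function(coh, band = c(4, 8), high_thresh = 0.6) {
  sel <- coh$freq >= band[1] & coh$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  bm <- mean(coh$coh[, sel])
  list(band_mean = bm, high_pair = bm > high_thresh)
}

#' Band coherence for every M1 x DLS electrode pair of one period
#'
#' Applies common-median referencing and z-scoring, drops artifact
#' channels, and computes NREM band coherence for each cross-region pair.
#'
#' @param s a [session()]; @param hyp hypnogram of the period.
#' @param band Hz band (default 4-8); @param reference apply common-median
#'   referencing (default TRUE).
#' @return data.frame: `m1_channel`, `dls_channel`, `pair`, `period`, `day`,
#'   `band_mean`, `high_pair`, `n_windows`.
#' @export
session_coherence_panel <- function(s, hyp, band = c(4, 8),
                                    reference = TRUE) {
  lfp <- s$lfp
  keep <- artifact_channel_mask(lfp)
  if (reference)
    lfp <- common_median_reference(lfp, s$channel_region)
  lfp <- zscore_channels(lfp)
  m1 <- which(s$channel_region == "M1" & keep)
  dls <- which(s$channel_region == "DLS" & keep)
  rows <- list()
  for (i in m1) for (j in dls) {
    co <- nrem_coherence(lfp[i, ], lfp[j, ], s$sampling_rate, hyp)
    bm <- coherence_band_mean(co, band)
    rows[[length(rows) + 1]] <-
      data.frame(m1_channel = i, dls_channel = j,
                 pair = paste0("ch", i, "-ch", j),
                 period = hyp$period, day = s$day_index,
                 band_mean = bm$band_mean, high_pair = bm$high_pair,
                 n_windows = co$n_windows)
  }
  do.call(rbind, rows)
}

#' Online/offline decomposition of multiday coherence
#'
#' For a per-pair series of band means over days and periods:
#' online change on day d is `post_d - pre_d`; offline change across the
#' following night is `pre_(d+1) - post_d`. The total change is
#' `pre_last - pre_first`, which equals the sum of all offline changes plus
#' the online changes of all but the last day (exact telescoping). The
#' trend class applies a +/- `dead_zone` band to the total change.
#'
#' @param panel data.frame with columns `pair`, `day`, `period`
#'   (`"pre"`/`"post"`) and `band_mean`, covering >= 2 days.
#' @param dead_zone no-change half-width (default 0.025).
#' @return data.frame per pair: mean online and offline change,
#'   `total_change`, `trend` in `increase`/`decrease`/`no-change`.
#' @export
online_offline_decomposition <- function(panel, dead_zone = 0.025) {
  out <- lapply(split(panel, panel$pair), function(pp) {
    days <- sort(unique(pp$day))
    if (length(days) < 2) stop("need >= 2 days for pair ", pp$pair[1])
    getv <- function(d, per) {
      v <- pp$band_mean[pp$day == d & pp$period == per]
      if (length(v) != 1) stop("missing ", per, " on day ", d,
                               " for pair ", pp$pair[1])
      v
    }
    pre <- vapply(days, getv, 0, per = "pre")
    post <- vapply(days, getv, 0, per = "post")
    online <- post - pre
    offline <- pre[-1] - post[-length(post)]
    total <- pre[length(pre)] - pre[1]
    trend <- if (total > dead_zone) "increase"
             else if (total < -dead_zone) "decrease" else "no-change"
    data.frame(pair = pp$pair[1],
               online_mean = mean(online), offline_mean = mean(offline),
               sum_online_except_last = sum(online[-length(online)]),
               sum_offline = sum(offline),
               total_change = total, trend = trend)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' NREM 4-8 Hz phase-difference distribution between two LFP signals
#'
#' Both signals are band-pass filtered (zero-phase FIR), their analytic
#' phases extracted, and the wrapped difference collected over all NREM
#' samples.
#'
#' @param x,y LFP signals (recording time); @param fs Hz.
#' @param hyp hypnogram; @param band Hz band (default 4-8).
#' @return list with `mean` (circular mean), `resultant`, `rayleigh_p` and
#'   the sampled `differences` (radians).
#' @export
phase_difference <- function(x, y, fs, hyp, band = c(4, 8)) {
  phx <- Arg(hilbert_analytic(fir_bandpass(x, band, fs)))
  phy <- Arg(hilbert_analytic(fir_bandpass(y, band, fs)))
  iv <- state_intervals(hyp, "NREM")
  if (!nrow(iv)) stop("no NREM samples")
  t <- (seq_along(x) - 1) / fs
  sel <- in_intervals(t, iv)
  d <- wrap_angle(phx[sel] - phy[sel])
  ray <- rayleigh_test(if (length(d) > 20000)
    d[seq(1, length(d), length.out = 20000)] else d)
  list(mean = circ_mean(d), resultant = circ_resultant(d),
       rayleigh_p = ray$p, differences = d)
}
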