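## DLS spike locking to 4-8 Hz M1 LFP phase, quantified by the circular
## standard deviation (cSD) of the spike-phase distribution: lower cSD =
## stronger locking.

#' Instantaneous band phase of an LFP signal
#'
#' Zero-phase FIR band-pass (3-cycle order heuristic) followed by the
#' analytic-signal phase. Phase 0 corresponds to the filtered-signal
#' positive peak.
#'
#' @param x signal; @param band `c(lo, hi)` Hz; @param fs Hz.
#' @param order optional FIR order override.
#' @return phase in (-pi, pi] per sample.
#' @export
bandpass_phase <- function(x, band = c(4, 8), fs, order = NULL) {
  if (band[2] >= fs / 2) stop("band must lie below Nyquist")
  Arg(hilbert_analytic(fir_bandpass(x, band, fs, order)))
}

#' Spike-phase histogram and circular standard deviation
#'
#' Phases are sampled at each spike time (nearest LFP sample) restricted to
#' the supplied intervals (typically NREM bouts). cSD is computed from the
#' raw phases, `sqrt(-2 log Rbar)`; the 20-bin histogram is descriptive
#' only.
#'
#' @param spike_times seconds; @param phase per-sample phase from
#'   [bandpass_phase()]; @param fs Hz.
#' @param intervals half-open intervals restricting spikes (matrix or
#'   NULL for all).
#' @param n_bins histogram bins (default 20).
#' @param min_spikes below this the result is flagged `low_n` (default 10).
#' @return list: `n_spikes`, `csd`, `rayleigh_p`, `mean_phase`,
#'   `histogram` (`breaks`, `counts`), `low_n`.
#' @export
spike_phase_csd <- function(spike_times, phase, fs, intervals = NULL,
                            n_bins = 20, min_spikes = 10) {
  if (!is.null(intervals))
    spike_times <- spike_times[in_intervals(spike_times, intervals)]
  if (length(spike_times) == 0) stop("no spikes in the analysis intervals")
  idx <- pmin(pmax(round(spike_times * fs) + 1, 1), length(phase))
  ph <- phase[idx]
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(ph, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  ray <- rayleigh_test(ph)
  list(n_spikes = length(ph),
       csd = circ_sd(ph),
       rayleigh_p = ray$p,
       mean_phase = circ_mean(ph),
       histogram = list(breaks = breaks, counts = counts),
       low_n = length(ph) < min_spikes)
}

#' Phase locking of every DLS unit to every M1 channel
#'
#' @param s a [session()]; @param hyp hypnogram (NREM restriction).
#' @param band Hz band (default 4-8).
#' @return data.frame: `m1_channel`, `dls_unit`, `n_spikes`, `csd`,
#'   `rayleigh_p`, `low_n`.
#' @export
session_phase_locking <- function(s, hyp, band = c(4, 8)) {
  iv <- state_intervals(hyp, "NREM")
  m1 <- which(s$channel_region == "M1")
  dls_units <- Filter(function(u) u$region == "DLS", s$units)
  rows <- list()
  for (ch in m1) {
    ph <- bandpass_phase(s$lfp[ch, ], band, s$sampling_rate)
    for (u in dls_units) {
      res <- tryCatch(
        spike_phase_csd(u$spike_times, ph, s$sampling_rate, iv),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <-
        data.frame(m1_channel = ch, dls_unit = u$unit_id,
                   n_spikes = res$n_spikes, csd = res$csd,
                   rayleigh_p = res$rayleigh_p, low_n = res$low_n)
    }
  }
  do.call(rbind, rows)
}

#' Relate per-channel mean cSD to per-channel mean band coherence
#'
#' For each M1 channel, the mean cSD across its DLS units is paired with
#' the mean M1-DLS band coherence across DLS electrodes; the Pearson
#' correlation across channels is reported (undefined with < 3 channels or
#' zero variance, flagged).
#'
#' @param locking data.frame from [session_phase_locking()].
#' @param panel data.frame from [session_coherence_panel()].
#' @return list with per-channel `points` data.frame and `pearson_r`.
#' @export
locking_vs_coherence <- function(locking, panel) {
  ch <- intersect(unique(locking$m1_channel), unique(panel$m1_channel))
  if (!length(ch)) stop("no shared M1 channels")
  pts <- do.call(rbind, lapply(ch, function(c0) {
    data.frame(m1_channel = c0,
               mean_csd = mean(locking$csd[locking$m1_channel == c0]),
               mean_coherence = mean(panel$band_mean[panel$m1_channel == c0]))
  }))
  r <- NA_real_
  defined <- nrow(pts) >= 3 &&
    stats::sd(pts$mean_csd) > 0 && stats::sd(pts$mean_coherence) > 0
  if (defined) r <- stats::cor(pts$mean_csd, pts$mean_coherence)
  list(points = pts, pearson_r = r, defined = defined)
}
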