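## Offline behavioral state classification: wake / NREM / REM in 10 s
## epochs from mean M1 LFP delta power (1-4 Hz), theta ratio
## (5-10 / 2-15 Hz) and movement, with a 60 s minimum-bout rule.

STATES <- c("wake", "NREM", "REM")

#' Construct a hypnogram
#' @param labels character vector over `"wake"`, `"NREM"`, `"REM"`.
#' @param period period label (`"pre"`, `"post"`, ...).
#' @param start_s recording time of the first epoch's start (seconds).
#' @param epoch_s epoch length, fixed at 10 s by convention.
#' @export
hypnogram <- function(labels, period = "pre", start_s = 0, epoch_s = 10) {
  if (!all(labels %in% STATES)) stop("unknown state label")
  structure(list(labels = as.character(labels), period = period,
                 start_s = start_s, epoch_s = epoch_s),
            class = "cs_hypnogram")
}

#' @export
print.cs_hypnogram <- function(x, ...) {
  tb <- table(factor(x$labels, STATES))
  cat(sprintf("<hypnogram %s: %d epochs x %gs | wake %d, NREM %d, REM %d>\n",
              x$period, length(x$labels), x$epoch_s,
              tb["wake"], tb["NREM"], tb["REM"]))
  invisible(x)
}

#' Epoch intervals of a hypnogram in a given state
#' @param h a [hypnogram()]; @param state state label.
#' @return matrix of half-open `[start, end)` intervals in recording time,
#'   merged over consecutive epochs.
#' @export
state_intervals <- function(h, state = "NREM") {
  sel <- h$labels == state
  if (!any(sel)) return(matrix(numeric(0), 0, 2))
  st <- h$start_s + (which(sel) - 1) * h$epoch_s
  interval_union(cbind(st, st + h$epoch_s))
}

#' Average LFP across a region's channels
#' @param s a [session()]; @param region `"M1"` or `"DLS"`.
#' @return numeric vector, the sample-wise mean signal.
#' @export
mean_region_lfp <- function(s, region) {
  sel <- s$channel_region == region
  if (!any(sel)) stop("no channels in region ", region)
  colMeans(s$lfp[sel, , drop = FALSE])
}

#' Per-window state features (delta power and theta ratio)
#'
#' Multitaper PSD in non-overlapping 10 s windows; delta power is the mean
#' PSD over 1-4 Hz, theta ratio the mean 5-10 Hz PSD over the mean
#' 2-15 Hz PSD (band edges closed on the 0.1 Hz grid).
#'
#' @param x mean LFP signal for one period.
#' @param fs sampling rate (Hz).
#' @param start_s recording time of `x[1]`, carried into window timestamps.
#' @param nw,k multitaper parameters (defaults 3 and 5).
#' @return data.frame with `window_start_s`, `delta_power`, `theta_ratio`.
#' @export
compute_state_features <- function(x, fs, start_s = 0, nw = 3, k = 5) {
  r <- mt_psd(x, fs, window_s = 10, nw = nw, k = k)
  bsum <- function(band) {
    sel <- r$freq >= band[1] & r$freq <= band[2]
    rowSums(r$psd[, sel, drop = FALSE])
  }
  ## theta ratio uses band integrals so it lives in [0, 1]
  data.frame(window_start_s = start_s + r$window_start_s,
             delta_power = band_power(r$freq, r$psd, c(1, 4)),
             theta_ratio = bsum(c(5, 10)) / bsum(c(2, 15)))
}

#' Classify 10 s epochs into wake / NREM / REM
#'
#' Thresholds are the within-period means of delta power and theta ratio.
#' Rules, in order: NREM if delta above mean and no movement; else REM if
#' theta ratio above mean and delta below mean; else wake. The REM rule
#' carries no movement condition (documented choice: the staging procedure
#' states none).
#'
#' @param features data.frame from [compute_state_features()].
#' @param movement logical vector, one flag per window.
#' @param period,start_s metadata forwarded to the [hypnogram()].
#' @export
classify_states <- function(features, movement, period = "pre",
                            start_s = features$window_start_s[1]) {
  if (nrow(features) != length(movement))
    stop("features and movement length mismatch")
  mdelta <- mean(features$delta_power)
  mtheta <- mean(features$theta_ratio)
  lab <- rep("wake", nrow(features))
  nrem <- features$delta_power > mdelta & !movement
  rem <- !nrem & features$theta_ratio > mtheta & features$delta_power < mdelta
  lab[rem] <- "REM"
  lab[nrem] <- "NREM"
  hypnogram(lab, period, start_s)
}

#' Enforce the 60 s minimum sleep-bout rule
#'
#' Every maximal run of NREM or REM shorter than six consecutive epochs is
#' reclassified as wake. Idempotent; wake runs are never touched.
#' @param h a [hypnogram()]; @param min_epochs minimum run length (6).
#' @export
enforce_min_bout <- function(h, min_epochs = 6L) {
  lab <- h$labels
  r <- rle(lab)
  short <- r$values %in% c("NREM", "REM") & r$lengths < min_epochs
  r$values[short] <- "wake"
  hypnogram(inverse.rle(r), h$period, h$start_s, h$epoch_s)
}

#' Stage one period of a session
#'
#' Convenience wrapper: mean M1 LFP -> features -> rule-based labels ->
#' minimum-bout rule.
#' @param s a [session()]; @param period `"pre"` or `"post"`.
#' @param nw,k multitaper parameters.
#' @export
stage_period <- function(s, period = "pre", nw = 3, k = 5) {
  p <- s$periods[[period]]
  if (is.null(p)) stop("unknown period ", period)
  m1 <- mean_region_lfp(s, "M1")
  i0 <- round(p[1] * s$sampling_rate) + 1
  i1 <- round(p[2] * s$sampling_rate)
  x <- m1[i0:i1]
  feats <- compute_state_features(x, s$sampling_rate, start_s = p[1],
                                  nw = nw, k = k)
  mv <- s$movement[[period]]
  if (is.null(mv)) stop("no movement flags for period ", period)
  mv <- mv[seq_len(nrow(feats))]
  enforce_min_bout(classify_states(feats, mv, period, p[1]))
}

#' Sleep-depth profile (1-4 Hz power, duration-normalised)
#'
#' Per-window low-frequency power over a period, linearly interpolated onto
#' a fixed-length grid so halves/periods of different durations are
#' comparable.
#'
#' @param x mean M1 LFP for the period; @param fs Hz.
#' @param grid_n output grid length per period (default 100).
#' @param nw,k multitaper parameters.
#' @return numeric vector of length `grid_n`.
#' @export
sleep_depth_profile <- function(x, fs, grid_n = 100, nw = 3, k = 5) {
  if (length(x) < 10 * fs) stop("period shorter than one 10 s window")
  r <- mt_psd(x, fs, window_s = 10, nw = nw, k = k)
  p <- band_power(r$freq, r$psd, c(1, 4))
  if (length(p) == 1) return(rep(p, grid_n))
  stats::approx(seq_along(p), p, xout = seq(1, length(p),
                length.out = grid_n))$y
}
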