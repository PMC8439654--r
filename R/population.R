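## Cross-area population dynamics during action execution: PCA
## trajectories of DLS activity around pellet touch, predicted from the
## preceding 1.5 s of M1 spiking with cross-validated linear models, and a
## per-unit task-modulation index.

#' Bin spiking into a units x trials x bins tensor around pellet touch
#'
#' Bins are half-open `[t, t + bin_s)` relative to touch; with the default
#' window `[-5, 5)` and 100 ms bins, touch falls on the bin 50/51 boundary.
#' Trials whose window leaves the recording are dropped (with a message).
#'
#' @param units list of [unit()] records (already filtered to one region,
#'   or mixed -- see `region`).
#' @param touch_times pellet-touch times (seconds).
#' @param region optional region filter (`"M1"`/`"DLS"`).
#' @param window `c(lo, hi)` seconds around touch (default `c(-5, 5)`).
#' @param bin_s bin width (default 0.1).
#' @param recording_dur_s recording length, for bounds checking
#'   (default `Inf`).
#' @return list: `counts` (array units x trials x bins), `unit_ids`,
#'   `regions`, `touch_times` (kept trials), `window`, `bin_s`.
#' @export
build_trial_tensor <- function(units, touch_times, region = NULL,
                               window = c(-5, 5), bin_s = 0.1,
                               recording_dur_s = Inf) {
  if (!is.null(region)) units <- Filter(function(u) u$region == region, units)
  if (!length(units)) stop("no units to bin")
  ok <- touch_times + window[1] >= 0 &
        touch_times + window[2] <= recording_dur_s
  if (any(!ok)) message(sum(!ok), " trial(s) dropped: window out of bounds")
  touch_times <- touch_times[ok]
  if (!length(touch_times)) stop("no trials remain")
  nb <- round((window[2] - window[1]) / bin_s)
  arr <- array(0, dim = c(length(units), length(touch_times), nb))
  edges0 <- window[1]
  for (ui in seq_along(units)) {
    st <- units[[ui]]$spike_times
    for (ti in seq_along(touch_times)) {
      rel <- st - touch_times[ti]
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel))
        arr[ui, ti, ] <- tabulate(floor((rel - edges0) / bin_s) + 1, nb)
    }
  }
  list(counts = arr,
       unit_ids = vapply(units, function(u) u$unit_id, ""),
       regions = vapply(units, function(u) u$region, ""),
       touch_times = touch_times, window = window, bin_s = bin_s)
}

#' Low-dimensional DLS trial trajectories by PCA
#'
#' Components are fit on the trial-concatenated full-window matrix (time
#' bins as observations, units as variables, per-unit mean centring, no
#' scaling); scores are evaluated on the reach sub-window.
#'
#' @param tensor a tensor from [build_trial_tensor()] (DLS units).
#' @param n_components number of components (default 3).
#' @param score_window sub-window for trajectories (default `c(-1, 1)` s).
#' @param min_units minimum unit count (default 7).
#' @return list of class `cs_trajmodel`: `loadings` (units x comps),
#'   `scores` (array trials x score-bins x comps), `explained` (variance
#'   fractions), `score_bins` (bin indices into the tensor), `center`.
#' @export
dls_trajectories <- function(tensor, n_components = 3,
                             score_window = c(-1, 1), min_units = 7) {
  d <- dim(tensor$counts)
  if (d[1] < min_units)
    stop("need at least ", min_units, " units, have ", d[1])
  if (d[1] < n_components) stop("fewer units than components")
  ## time bins x units, trials concatenated
  X <- t(matrix(tensor$counts, d[1], d[2] * d[3]))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_components), drop = FALSE]
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  centers <- tensor$window[1] + (seq_len(d[3]) - 0.5) * tensor$bin_s
  sb <- which(centers > score_window[1] & centers < score_window[2])
  scores <- array(0, dim = c(d[2], length(sb), n_components))
  for (ti in seq_len(d[2])) {
    M <- sweep(t(tensor$counts[, ti, sb, drop = TRUE]), 2, ctr)
    scores[ti, , ] <- M %*% W
  }
  structure(list(loadings = W, scores = scores,
                 explained = expl[seq_len(n_components)],
                 score_bins = sb, center = ctr,
                 window = score_window),
            class = "cs_trajmodel")
}

#' Cross-validated prediction of DLS trajectories from M1 history
#'
#' For each predicted time bin, the predictors are the preceding 1.5 s of
#' every M1 unit's spiking (15 lag bins x units). One linear model per
#' component; trials are partitioned into `folds` contiguous blocks, and
#' held-out predictions are concatenated before correlating with the
#' actual trajectories.
#'
#' @param model a `cs_trajmodel` from [dls_trajectories()].
#' @param m1_tensor M1 tensor from [build_trial_tensor()]; its window must
#'   cover 1.5 s before every predicted bin.
#' @param folds number of CV folds (default 5).
#' @param history_s predictor history length (default 1.5).
#' @param min_units minimum M1 unit count (default 7).
#' @return list: `score` (mean over components of Pearson r),
#'   `component_r`, `predicted` and `actual` matrices.
#' @export
predict_trajectory <- function(model, m1_tensor, folds = 5,
                               history_s = 1.5, min_units = 7) {
  d <- dim(m1_tensor$counts)
  if (d[1] < min_units) stop("need at least ", min_units, " M1 units")
  n_trials <- dim(model$scores)[1]
  if (d[2] != n_trials) stop("trial count mismatch between tensors")
  if (n_trials < folds) stop("fewer trials than folds")
  nlag <- round(history_s / m1_tensor$bin_s)
  ## predicted-bin centres in the DLS tensor coordinate frame
  sb <- model$score_bins
  ## map to M1 tensor bins via the shared touch-relative time axis
  ## (both tensors are touch-aligned; bin i covers window[1]+(i-1)*bin)
  offset <- round((model$window[1] - m1_tensor$window[1]) /
                  m1_tensor$bin_s)
  ## m1 bin index corresponding to DLS score bin k (same width assumed)
  dls_window_lo <- sb[1]   # index into DLS tensor
  m1_idx_of <- function(k) offset + (k - sb[1]) + 1L
  first_needed <- m1_idx_of(sb[1]) - nlag + 0L
  if (first_needed < 1)
    stop("M1 tensor window too short for the history of the first bin")
  nb_pred <- length(sb)
  ## build design: rows = (trial, predicted bin), cols = unit x lag
  rows <- n_trials * nb_pred
  Xd <- matrix(0, rows, d[1] * nlag)
  for (ti in seq_len(n_trials)) {
    m1m <- m1_tensor$counts[, ti, , drop = TRUE]   # units x bins
    for (bi in seq_len(nb_pred)) {
      mb <- m1_idx_of(sb[bi])
      h <- m1m[, (mb - nlag):(mb - 1), drop = FALSE]
      Xd[(ti - 1) * nb_pred + bi, ] <- as.vector(h)
    }
  }
  fold_id <- rep(cut(seq_len(n_trials), folds, labels = FALSE),
                 each = nb_pred)
  ncomp <- dim(model$scores)[3]
  pred <- matrix(NA_real_, rows, ncomp)
  actual <- matrix(NA_real_, rows, ncomp)
  for (ci in seq_len(ncomp)) {
    yv <- as.vector(t(model$scores[, , ci]))   # trial-major, bin within
    actual[, ci] <- yv
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- fold_id == f
      fit <- stats::lm.fit(cbind(1, Xd[tr, , drop = FALSE]), yv[tr])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred[te, ci] <- cbind(1, Xd[te, , drop = FALSE]) %*% beta
    }
  }
  comp_r <- vapply(seq_len(ncomp), function(ci)
    stats::cor(actual[, ci], pred[, ci]), 0)
  list(score = mean(comp_r), component_r = comp_r,
       predicted = pred, actual = actual)
}

#' Task-modulation index of a unit
#'
#' Trial-averaged 25 ms PETH over -5..+5 s around touch, z-scored; the
#' index is the summed |z| over (-1, +0.5) s divided by the summed |z|
#' over the (-3.5, -2) s baseline (both 60 bins).
#'
#' @param spike_times seconds; @param touch_times trial touch times.
#' @param min_trials minimum trial count (default 10).
#' @return list: `index` (`NA` + `undefined` when the PETH has zero
#'   variance), `z` (400-bin z-scored PETH), `bin_centers`.
#' @export
unit_modulation_index <- function(spike_times, touch_times,
                                  min_trials = 10) {
  if (length(touch_times) < min_trials)
    stop("need at least ", min_trials, " trials")
  bin_s <- 0.025
  p <- event_peth(spike_times, touch_times, window = c(-5, 5),
                  bin_s = bin_s)
  if (stats::sd(p$rate) == 0)
    return(list(index = NA_real_, undefined = TRUE, z = NULL,
                bin_centers = p$bin_centers))
  z <- (p$rate - mean(p$rate)) / stats::sd(p$rate)
  ctr <- p$bin_centers
  num <- sum(abs(z[ctr > -1 & ctr < 0.5]))
  den <- sum(abs(z[ctr > -3.5 & ctr < -2]))
  list(index = num / den, undefined = FALSE, z = z, bin_centers = ctr)
}
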