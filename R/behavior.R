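## Reach-to-grasp kinematics: velocity profiles, convergence to the
## last-day template, learning summaries, the AP5/saline permutation test
## and the connectivity-behavior (partial) correlation.

#' Per-trial velocity profile around pellet touch
#'
#' First-difference velocities (frame-to-frame displacement times frame
#' rate), clipped to the 1 s window centred on the touch frame.
#'
#' @param x,y hand positions per frame.
#' @param frame_rate Hz; @param touch_frame index of pellet touch.
#' @return list: `vx`, `vy` (length ~ `frame_rate`), `t` (seconds relative
#'   to touch).
#' @export
velocity_profile <- function(x, y, frame_rate, touch_frame) {
  hw <- round(0.5 * frame_rate)
  lo <- touch_frame - hw; hi <- touch_frame + hw - 1
  if (lo < 1 || hi + 1 > length(x))
    stop("1 s window around touch exceeds the trajectory")
  idx <- lo:hi
  list(vx = (x[idx + 1] - x[idx]) * frame_rate,
       vy = (y[idx + 1] - y[idx]) * frame_rate,
       t = (idx - touch_frame) / frame_rate)
}

## resample a profile to a common rate (linear interpolation)
resample_profile <- function(v, t, rate = 100) {
  tt <- seq(min(t), max(t), by = 1 / rate)
  stats::approx(t, v, xout = tt)$y
}

#' Mean velocity profile of one day
#'
#' @param trials list of per-trial lists with `x`, `y`, `frame_rate`,
#'   `touch_frame` (and optionally `success`; unsuccessful trials are
#'   excluded).
#' @param rate common resampling rate (default 100 samples/s).
#' @return list with mean `vx`, `vy` on the common grid and `n_trials`.
#' @export
day_mean_profile <- function(trials, rate = 100) {
  keep <- Filter(function(tr) is.null(tr$success) || tr$success, trials)
  if (!length(keep)) stop("no successful trials")
  profs <- lapply(keep, function(tr) {
    v <- velocity_profile(tr$x, tr$y, tr$frame_rate, tr$touch_frame)
    list(vx = resample_profile(v$vx, v$t, rate),
         vy = resample_profile(v$vy, v$t, rate))
  })
  n <- min(vapply(profs, function(p) length(p$vx), 0L))
  list(vx = rowMeans(vapply(profs, function(p) p$vx[seq_len(n)],
                            numeric(n))),
       vy = rowMeans(vapply(profs, function(p) p$vy[seq_len(n)],
                            numeric(n))),
       n_trials = length(keep))
}

#' Correlation of each day's mean profile with the template day
#'
#' Pearson correlations computed separately for x and y then averaged.
#'
#' @param day_profiles list (one per day) of lists with `vx`, `vy` on a
#'   shared grid.
#' @param template_day index of the template day (default last).
#' @return numeric vector `r_d`, one per day (template day = 1 by
#'   construction).
#' @export
template_correlation <- function(day_profiles,
                                 template_day = length(day_profiles)) {
  tp <- day_profiles[[template_day]]
  if (stats::sd(tp$vx) == 0 || stats::sd(tp$vy) == 0)
    stop("zero-variance template profile")
  vapply(day_profiles, function(p)
    (stats::cor(p$vx, tp$vx) + stats::cor(p$vy, tp$vy)) / 2, 0)
}

#' Total change in template correlation over training
#'
#' The template day (the last) is excluded, so the change is the
#' second-to-last day's correlation minus the first day's.
#' @param r_d per-day correlations, template day last.
#' @export
total_correlation_change <- function(r_d) {
  if (length(r_d) < 3) stop("need at least 3 days")
  r <- r_d[-length(r_d)]
  r[length(r)] - r[1]
}

#' Permutation test for an infusion effect on day-to-day changes
#'
#' Statistic: mean change under AP5 minus mean change under saline. Labels
#' are reshuffled `n_perm` times; the raw percentile of the real statistic
#' within the permutation distribution is reported together with the
#' two-sided `p = 2 min(q, 1 - q)`.
#'
#' @param changes numeric day-to-day changes.
#' @param labels `"AP5"`/`"saline"` per change.
#' @param n_perm permutations (default 10000); @param seed RNG seed.
#' @return list: `statistic`, `percentile`, `p_two_sided`, `perm_stats`.
#' @export
infusion_permutation_test <- function(changes, labels, n_perm = 10000,
                                      seed = NULL) {
  if (length(unique(labels)) < 2) stop("need both AP5 and saline labels")
  if (!is.null(seed)) set.seed(seed)
  stat_fn <- function(lab) mean(changes[lab == "AP5"]) -
                           mean(changes[lab == "saline"])
  real <- stat_fn(labels)
  perm <- vapply(seq_len(n_perm), function(i) stat_fn(sample(labels)), 0)
  q <- mean(perm <= real)
  list(statistic = real, percentile = q,
       p_two_sided = min(1, 2 * min(q, 1 - q)), perm_stats = perm)
}

#' Coherence-behavior correlation with peak-velocity control
#'
#' Day series are z-scored within each animal, pooled, and the Pearson
#' correlation between coherence and template correlation computed; the
#' partial correlation controlling peak velocity uses the standard
#' residual-correlation identity.
#'
#' @param df data.frame with columns `animal`, `day`, `coherence`, `r_d`,
#'   `peak_velocity`; needs >= 4 days per animal.
#' @return list: `pearson_r`, `partial_r`, `n`.
#' @export
connectivity_behavior_correlation <- function(df) {
  zs <- function(v) {
    if (stats::sd(v) == 0) stop("constant series within animal")
    (v - mean(v)) / stats::sd(v)
  }
  parts <- lapply(split(df, df$animal), function(a) {
    if (nrow(a) < 4) stop("need >= 4 days per animal")
    data.frame(x = zs(a$coherence), y = zs(a$r_d),
               z = zs(a$peak_velocity))
  })
  d <- do.call(rbind, parts)
  rxy <- stats::cor(d$x, d$y)
  rxz <- stats::cor(d$x, d$z)
  ryz <- stats::cor(d$y, d$z)
  list(pearson_r = rxy,
       partial_r = (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
       n = nrow(d))
}
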