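## Shared fixtures: everything is generated in code at test time.

## hypnogram covering `n` epochs of a single state
flat_hyp <- function(state = "NREM", n = 60, period = "pre", start_s = 0) {
  hypnogram(rep(state, n), period, start_s)
}

## small but fully valid session for I/O and plumbing tests
tiny_session <- function(seed = 1, fs = 100, dur = 120) {
  set.seed(seed)
  n <- fs * dur
  lfp <- matrix(rnorm(4 * n), 4, n)
  session("tiny", fs, lfp, c("M1", "M1", "DLS", "DLS"),
          units = list(unit("u1", "M1", sort(runif(50, 0, dur))),
                       unit("u2", "DLS", sort(runif(40, 0, dur)))),
          periods = list(pre = c(0, 40), train = c(40, 80),
                         post = c(80, 120)),
          movement = list(pre = rep(FALSE, 4), post = rep(TRUE, 4)),
          trials = data.frame(trial_id = "t1", touch_time_s = 60),
          day_index = 1L)
}

## homogeneous Poisson spike train on [0, dur)
rpois_train <- function(rate, dur, t0 = 0) {
  t0 + sort(runif(rpois(1, rate * dur), 0, dur))
}

## scaled-down default config used across tests (250 Hz, minutes not hours)
test_config <- function(seed = 1, ...) {
  args <- list(seed = seed, sampling_rate = 250,
               period_s = c(pre = 1200, train = 300, post = 1200),
               n_days = 2L, n_m1_channels = 3L, n_dls_channels = 3L,
               n_m1_units = 4L, n_dls_units = 4L, n_trials = 20L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

## phase unwrapping used by filter/phase tests
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

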