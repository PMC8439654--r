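## construct an M1 train plus a DLS train with planted excess-spike
## coupling at a fixed lag
coupled_pair <- function(dur = 600, r_m1 = 5, r_dls = 3, lag = 0.006,
                         p_excess = 0.1, jit = 0.001) {
  m1 <- rpois_train(r_m1, dur)
  pick <- runif(length(m1)) < p_excess
  extra <- m1[pick] + lag + rnorm(sum(pick), 0, jit)
  dls <- sort(c(rpois_train(r_dls, dur), extra))
  dls <- dls[dls > 0 & dls < dur]
  list(m1 = m1, dls = unique(dls))
}

test_that("CCG basics: self-copy, planted lag, chance level", {
  set.seed(40)
  iv <- matrix(c(0, 600), 1)
  m1 <- rpois_train(5, 600)
  cc0 <- cross_correlogram(m1, m1, iv)
  expect_equal(cc0$lags_ms[which.max(cc0$counts)], 0)
  shifted <- m1 + 0.006
  cc6 <- cross_correlogram(m1, shifted[shifted < 600], iv)
  expect_equal(cc6$lags_ms[which.max(cc6$counts)], 6)
  ## independent Poisson: mean count/bin ~ r1 * r2 * T * 0.001
  dls <- rpois_train(3, 600)
  cci <- cross_correlogram(m1, dls, iv)
  expected <- 5 * 3 * 600 * 0.001
  expect_equal(mean(cci$counts), expected, tolerance = 4 * sqrt(expected) /
                 sqrt(length(cci$counts)))
  expect_error(cross_correlogram(numeric(0), dls, iv), "no spikes")
})

test_that("lag-sign convention: M1-leads never yields negative-lag peaks", {
  set.seed(41)
  for (i in 1:5) {
    p <- coupled_pair(300, p_excess = 0.2)
    cc <- cross_correlogram(p$m1, p$dls, matrix(c(0, 300), 1))
    pk <- cc$lags_ms[which.max(cc$counts)]
    expect_gt(pk, 0)
    expect_lte(abs(pk - 6), 2)
  }
})

test_that("no cross-boundary lags across concatenated intervals", {
  ## spikes hugging a gap between intervals would produce a +5 ms lag if
  ## concatenation were naive
  m1 <- c(0.5, 9.9995)
  dls <- c(0.5060, 10.0040)
  iv <- rbind(c(0, 10), c(10, 20))
  cc <- cross_correlogram(m1, dls, iv)
  expect_equal(cc$counts[cc$lags_ms == 6], 1)   # within-interval pair only
  expect_equal(sum(cc$counts), 1)               # cross-gap pairs excluded
})

test_that("jitter surrogates: expectation matches Monte Carlo, structure rules", {
  set.seed(42)
  p <- coupled_pair(600)
  iv <- matrix(c(0, 600), 1)
  ens <- jitter_surrogates(p$m1, p$dls, iv, n_surrogates = 400, seed = 1)
  ## MC mean of the short-latency statistic equals the exact expectation
  exact <- mean(ens$mean_ccg[ens$lags_ms %in% 1:15]) / ens$n_m1
  expect_equal(mean(ens$surrogate_stats), exact, tolerance = 0.03)
  ## the planted 6 ms peak is flattened in the expected surrogate CCG
  real <- cross_correlogram(p$m1, p$dls, iv)
  sel <- real$lags_ms %in% 1:15
  expect_gt(mean(real$counts[sel]), 1.5 * mean(ens$mean_ccg[sel]))
  far <- abs(real$lags_ms) > 60
  expect_equal(mean(real$counts[far]), mean(ens$mean_ccg[far]),
               tolerance = 0.1 * mean(real$counts[far]))
  expect_warning(jitter_surrogates(p$m1, p$dls, iv, n_surrogates = 50),
                 "percentile")
})

test_that("jitter selectivity: slow structure kept, fine structure removed", {
  ## common slow rate modulation (period 400 ms) plus a genuine 6 ms
  ## synaptic copy: surrogates must reproduce the slow CCG landscape but
  ## not the short-latency peak
  set.seed(43)
  dur <- 900
  t_grid <- seq(0, dur, by = 0.001)
  lam <- 1 + 0.9 * sin(2 * pi * t_grid / 0.4)
  thin <- function(rate) {
    cand <- sort(runif(rpois(1, rate * 2 * dur), 0, dur))
    cand[runif(length(cand)) < lam[round(cand * 1000) + 1] / 2]
  }
  m1 <- thin(5)
  pick <- runif(length(m1)) < 0.1
  dls <- unique(sort(c(thin(5), m1[pick] + 0.006)))
  dls <- dls[dls < dur]
  iv <- matrix(c(0, dur), 1)
  real <- cross_correlogram(m1, dls, iv, max_lag_ms = 250)
  ens <- jitter_surrogates(m1, dls, iv, n_surrogates = 200,
                           max_lag_ms = 250, seed = 2, mc = FALSE)
  ## per-lag surrogate 95% band (counts are near-Poisson around the
  ## expected surrogate CCG): slow lags stay inside it
  slow <- abs(real$lags_ms) > 50
  mu <- ens$mean_ccg[slow]
  inside <- real$counts[slow] >= qpois(0.025, mu) &
            real$counts[slow] <= qpois(0.975, mu)
  expect_gt(mean(inside), 0.85)
  ## the 6 ms peak bursts far out of the band...
  mu6 <- ens$mean_ccg[ens$lags_ms == 6]
  expect_gt(real$counts[real$lags_ms == 6], qpois(0.9999, mu6))
  ## ...while the surrogate expectation is flat there (excess smeared over
  ## the 50 ms window): its short-lag contrast is a fraction of the real
  sel <- real$lags_ms %in% 1:15
  contrast <- function(v) max(v) - min(v)
  expect_lt(contrast(ens$mean_ccg[sel]), 0.3 * contrast(real$counts[sel]))
})

test_that("coupling verdict: planted coupling found, 100 ms lag excluded", {
  set.seed(44)
  hyp <- flat_hyp("NREM", 60, "pre")
  hyp2 <- flat_hyp("NREM", 60, "post")
  p <- coupled_pair(600)
  r <- detect_coupled(p$m1, p$dls, hyp, hyp2, n_surrogates = 500, seed = 3)
  expect_true(r$coupled)
  ## normalized CCG peaks at the planted lag
  expect_equal(r$lags_ms[which.max(r$normalized_ccg)], 6)
  ## coupling at 100 ms only -> not coupled (outside 1-15 ms window)
  m1 <- rpois_train(5, 600)
  pick <- runif(length(m1)) < 0.15
  dls <- sort(c(rpois_train(3, 600), m1[pick] + 0.1))
  dls <- unique(dls[dls < 600])
  r2 <- detect_coupled(m1, dls, hyp, hyp2, n_surrogates = 500, seed = 4)
  expect_false(r2$coupled)
  expect_error(detect_coupled(p$m1, p$dls, flat_hyp("NREM", 10), hyp2),
               "insufficient NREM")
})

test_that("normalized magnitude: null ~ 0, linear in excess, rate-robust", {
  set.seed(45)
  iv <- matrix(c(0, 600), 1)
  ## null at two rate levels
  for (r in c(2, 10)) {
    m1 <- rpois_train(r, 600); dls <- rpois_train(r, 600)
    nm <- normalized_magnitude(m1, dls, iv)
    expect_lt(abs(nm$magnitude), 4 * sqrt(r * 0.001 / 15 / length(m1)) + 5e-4)
  }
  ## linearity in excess probability (expected magnitude = p * (1-15/50) / 15)
  mag <- vapply(c(0.05, 0.1, 0.2), function(p0) {
    pp <- coupled_pair(600, p_excess = p0)
    normalized_magnitude(pp$m1, pp$dls, iv)$magnitude
  }, 0)
  theo <- c(0.05, 0.1, 0.2) * (1 - 15 / 50) / 15
  expect_equal(mag, theo, tolerance = 0.15)
  ## doubling the background rates leaves the magnitude unchanged
  p1 <- coupled_pair(600, r_m1 = 4, r_dls = 2)
  p2 <- coupled_pair(600, r_m1 = 8, r_dls = 4)
  m1v <- normalized_magnitude(p1$m1, p1$dls, iv)$magnitude
  m2v <- normalized_magnitude(p2$m1, p2$dls, iv)$magnitude
  expect_equal(m1v, m2v, tolerance = 0.3)
})

test_that("transmission by state and by rhythm resolve planted conditions", {
  set.seed(46)
  ## NREM in the first half, wake in the second; coupling only in NREM
  labels <- c(rep("NREM", 30), rep("wake", 30))
  hyp_pre <- hypnogram(labels, "pre", 0)
  hyp_post <- hypnogram(labels, "post", 600)
  m1 <- sort(c(rpois_train(5, 600), rpois_train(5, 600, t0 = 600)))
  nrem_iv <- rbind(c(0, 300), c(600, 900))
  in_nrem <- corticosleep:::in_intervals(m1, nrem_iv)
  pick <- runif(length(m1)) < 0.12 & in_nrem
  dls <- sort(c(rpois_train(3, 1200), m1[pick] + 0.006))
  dls <- unique(dls[dls < 1200])
  ts <- transmission_by_state(m1, dls, hyp_pre, hyp_post)
  expect_gt(ts$difference, 0)
  expect_gt(ts$NREM$magnitude, 3 * abs(ts$wake$magnitude))
  ## rhythm windows: gain planted only near "spindle" landmarks
  ev_sp <- seq(20, 280, by = 15)
  ev_so <- seq(320, 580, by = 15) # in wake half: no coupling there
  m1b <- rpois_train(5, 600)
  near_sp <- sapply(m1b, function(s) any(abs(s - ev_sp) < 0.5))
  pick2 <- runif(length(m1b)) < ifelse(near_sp, 0.25, 0)
  dlsb <- unique(sort(c(rpois_train(3, 600), m1b[pick2] + 0.006)))
  tr <- transmission_by_rhythm(m1b, dlsb,
                               list(spindle = ev_sp, SO = ev_so,
                                    delta = numeric(0)))
  expect_gt(tr$spindle$magnitude, tr$SO$magnitude + 0.002)
  expect_null(tr$delta)   # too few events -> skipped
})

test_that("half-period change detects a planted decay", {
  set.seed(47)
  dur <- 1200
  m1 <- rpois_train(5, dur)
  p_t <- ifelse(m1 < dur / 2, 0.2, 0.05)   # coupling decays at midpoint
  pick <- runif(length(m1)) < p_t
  dls <- unique(sort(c(rpois_train(3, dur), m1[pick] + 0.006)))
  hyp <- flat_hyp("NREM", dur / 10)
  hc <- half_period_change(m1, dls, c(0, dur), hyp)
  expect_lt(hc$change, 0)
  expect_equal(hc$second$magnitude / hc$first$magnitude, 0.25,
               tolerance = 0.2)
  ## stationary coupling -> change ~ 0
  pick2 <- runif(length(m1)) < 0.1
  dls2 <- unique(sort(c(rpois_train(3, dur), m1[pick2] + 0.006)))
  hc2 <- half_period_change(m1, dls2, c(0, dur), hyp)
  expect_lt(abs(hc2$change), 0.4 * hc2$first$magnitude)
})

test_that("peri-spindle curves are baseline-anchored and class-resolved", {
  set.seed(48)
  dur <- 3000
  ## spindles every ~200 s, alternating nesting class
  pk <- seq(100, dur - 100, by = 200)
  cls <- rep(c("SO-nested", "non-SO-nested"), length.out = length(pk))
  nesting <- data.frame(spindle_peak_s = pk, delay_s = 0.5, class = cls)
  m1 <- rpois_train(6, dur)
  ## coupling boosted in the 30 s after nested spindles only
  boost_iv <- cbind(pk[cls == "SO-nested"] + 1, pk[cls == "SO-nested"] + 31)
  in_boost <- corticosleep:::in_intervals(m1, boost_iv)
  pick <- runif(length(m1)) < ifelse(in_boost, 0.25, 0.05)
  dls <- unique(sort(c(rpois_train(3, dur), m1[pick] + 0.006)))
  res <- peri_spindle_transmission(m1, dls, nesting, c(0, dur))
  ## first bin exactly zero after baseline subtraction
  expect_equal(res$transmission[res$bin == 1], c(0, 0))
  post_bin <- res$bin == 4
  nested <- res$class == "SO-nested"
  expect_gt(res$transmission[post_bin & nested],
            res$transmission[post_bin & !nested] + 0.003)
  ## flat for the non-nested class
  expect_lt(max(abs(res$transmission[!nested])), 0.004)
})
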