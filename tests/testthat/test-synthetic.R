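test_that("hypnogram simulation: determinism, counts, degenerate configs", {
  cfg <- test_config(seed = 70)
  h1 <- simulate_hypnogram(cfg, "pre", 1)
  h2 <- simulate_hypnogram(cfg, "pre", 1)
  expect_identical(h1$labels, h2$labels)
  expect_length(h1$labels, 120)                    # 1200 s / 10 s
  expect_false(identical(h1$labels,
                         simulate_hypnogram(cfg, "post", 1)$labels))
  ## forcing p(NREM) = 1
  cfg_n <- test_config(seed = 70, state_dwell = c(wake = 0, NREM = 300,
                                                  REM = 0))
  expect_true(all(simulate_hypnogram(cfg_n, "pre", 1)$labels == "NREM"))
  ## sleep bouts are >= 6 epochs by construction
  r <- rle(h1$labels)
  expect_true(all(r$lengths[r$values %in% c("NREM", "REM")] >= 6))
  cfg_bad <- test_config(seed = 1, period_s = c(pre = 1205, train = 300,
                                                post = 1200))
  expect_error(simulate_hypnogram(cfg_bad, "pre", 1), "multiple")
})

test_that("planted rhythm events always lie inside NREM bouts", {
  for (seed in c(71, 72)) {
    cfg <- test_config(seed = seed)
    hyp <- simulate_hypnogram(cfg, "pre", 1)
    sim <- simulate_lfp(hyp, cfg, 1, "pre")
    iv <- state_intervals(hyp, "NREM")
    for (nm in c("spindle", "so", "delta")) {
      ev <- sim$events[[nm]]
      if (length(ev))
        expect_true(all(corticosleep:::in_intervals(ev, iv)),
                    label = paste(seed, nm))
    }
  }
})

test_that("state spectra separate: NREM delta > wake delta; REM theta high", {
  cfg <- test_config(seed = 73, period_s = c(pre = 2400, train = 300,
                                             post = 1200))
  hyp <- simulate_hypnogram(cfg, "pre", 1)
  sim <- simulate_lfp(hyp, cfg, 1, "pre")
  m1 <- colMeans(sim$lfp[sim$channel_region == "M1", ])
  f <- compute_state_features(m1, cfg$sampling_rate)
  lab <- hyp$labels[seq_len(nrow(f))]
  expect_gt(mean(f$delta_power[lab == "NREM"]),
            3 * mean(f$delta_power[lab == "wake"]))
  if (any(lab == "REM"))
    expect_gt(mean(f$theta_ratio[lab == "REM"]),
              2 * mean(f$theta_ratio[lab == "wake"]))
})

test_that("zero rhythm rates produce no planted events and no detections", {
  cfg <- test_config(seed = 74,
                     rhythm_rates = c(spindle = 0, SO = 0, delta = 0))
  hyp <- simulate_hypnogram(cfg, "pre", 1)
  sim <- simulate_lfp(hyp, cfg, 1, "pre")
  expect_length(sim$events$spindle, 0)
  m1 <- colMeans(sim$lfp[sim$channel_region == "M1", ])
  ## detector false positives on matched no-event noise are the detector's
  ## own chance level; with event-free thresholds they are rare but not 0
  spd <- detect_spindles(m1, cfg$sampling_rate, hyp)
  nrem_min <- corticosleep:::interval_duration(
    state_intervals(hyp, "NREM")) / 60
  expect_lt(nrow(spd) / nrem_min, 1)
})

test_that("spike simulation: Poisson counts, planted lag, determinism", {
  cfg <- test_config(seed = 75, phase_kappa = 0, spindle_mod_depth = 1)
  hyp <- simulate_hypnogram(cfg, "pre", 1)
  sim <- simulate_lfp(hyp, cfg, 1, "pre")
  spk1 <- simulate_spike_trains(cfg, sim, hyp, 1, "pre")
  spk2 <- simulate_spike_trains(cfg, sim, hyp, 1, "pre")
  expect_identical(spk1$units[[1]]$spike_times, spk2$units[[1]]$spike_times)
  ## count oracle: rate 5 Hz over 1200 s -> 6000 +/- 4 sqrt(6000)
  n1 <- length(spk1$units[[1]]$spike_times)
  expect_lt(abs(n1 - 6000), 4 * sqrt(6000))
  ## CCG of the planted coupled pair peaks at +6 ms
  m1u <- spk1$units[[1]]$spike_times
  dlsu <- spk1$units[[cfg$n_m1_units + 1]]$spike_times
  cc <- cross_correlogram(m1u, dlsu, matrix(c(0, 1200), 1))
  expect_lte(abs(cc$lags_ms[which.max(cc$counts)] - 6), 2)
  ## uncoupled unit: flat CCG
  dls2 <- spk1$units[[cfg$n_m1_units + 2]]$spike_times
  nm <- normalized_magnitude(m1u, dls2, matrix(c(0, 1200), 1))
  expect_lt(abs(nm$magnitude), 1e-3)
})

test_that("full sessions are deterministic and pass validation", {
  cfg <- test_config(seed = 76)
  s1 <- simulate_session(cfg, 1)
  s2 <- simulate_session(cfg, 1)
  expect_identical(s1$session$lfp, s2$session$lfp)
  expect_identical(lapply(s1$session$units, `[[`, "spike_times"),
                   lapply(s2$session$units, `[[`, "spike_times"))
  expect_silent(validate_session(s1$session))
  ## different day -> different data
  s3 <- simulate_session(cfg, 2)
  expect_false(identical(s1$session$lfp[1, 1:100],
                         s3$session$lfp[1, 1:100]))
})

test_that("reach simulation: convergence, freezing, degenerate blends", {
  cfg <- test_config(seed = 77, n_days = 6, n_trials = 12,
                     conv_start = 0.2, conv_rate = 0.15,
                     trial_noise_sd = 0.2)
  beh <- simulate_reach_days(cfg)
  profs <- lapply(beh$days, day_mean_profile)
  r <- template_correlation(profs)
  expect_equal(r[length(r)], 1, tolerance = 1e-9)
  expect_gt(total_correlation_change(r), 0.05)
  expect_true(all(diff(beh$truth$blend) >= 0))
  ## zero convergence rate: blend flat
  cfg0 <- test_config(seed = 77, n_days = 4, conv_rate = 0,
                      n_trials = 8)
  expect_true(all(diff(simulate_reach_days(cfg0)$truth$blend) == 0))
  ## AP5 freezes the blend weight
  cfg_ap5 <- test_config(seed = 78, n_days = 6, n_trials = 8,
                         ap5_days = 3:4)
  tr <- simulate_reach_days(cfg_ap5)$truth
  expect_equal(tr$blend[3], tr$blend[2])
  expect_equal(tr$blend[4], tr$blend[3])
  expect_gt(tr$blend[5], tr$blend[4])
  ## blend weight 1 + zero trial noise -> day equals template exactly
  cfg1 <- test_config(seed = 79, n_days = 3, n_trials = 5,
                      conv_start = 1, conv_rate = 0, trial_noise_sd = 0)
  b1 <- simulate_reach_days(cfg1)
  p <- lapply(b1$days, day_mean_profile)
  expect_equal(template_correlation(p)[1], 1, tolerance = 1e-9)
})

test_that("planted coherence SNR maps to NREM band coherence monotonely", {
  vals <- vapply(c(0.5, 4), function(snr) {
    cfg <- test_config(seed = 80, coherence_snr = snr,
                       period_s = c(pre = 1200, train = 300, post = 1200))
    hyp <- simulate_hypnogram(cfg, "pre", 1)
    sim <- simulate_lfp(hyp, cfg, 1, "pre")
    co <- nrem_coherence(sim$lfp[1, ], sim$lfp[4, ], cfg$sampling_rate,
                         hyp)
    coherence_band_mean(co)$band_mean
  }, 0)
  expect_gt(vals[2], vals[1] + 0.1)
  expect_gt(vals[2], 0.6)   # snr 4 -> theoretical 0.8
})
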