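test_that("background noise has the configured spectrum, scale and seed
           discipline", {
  cfg <- synthetic_config(n_channels = 4)
  bg <- generate_background(cfg, 60, seed = 201)
  # log-log PSD slope ~ -1 for the 1/f default
  ps <- spec.pgram(ts(bg$data[2, ], frequency = cfg$fs), spans = 25,
                   plot = FALSE, taper = 0.1)
  sel <- ps$freq > 1 & ps$freq < 100
  slope <- coef(lm(log(ps$spec[sel]) ~ log(ps$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.15)
  # RMS scaling and determinism
  expect_equal(apply(bg$data, 1, sd), rep(cfg$background_rms, 4),
               tolerance = 1e-9)
  cfg2 <- synthetic_config(n_channels = 4, background_rms = 60)
  bg2 <- generate_background(cfg2, 60, seed = 201)
  expect_equal(sd(bg2$data[1, ]), 2 * sd(bg$data[1, ]), tolerance = 1e-9)
  again <- generate_background(cfg, 60, seed = 201)
  expect_identical(bg$data, again$data)
})

test_that("injected event counts follow the configured Poisson rates", {
  # a coarsely sampled carrier recording keeps the repetitions cheap; the
  # Poisson draws depend only on the rates and the epoch windows
  cfg <- synthetic_config(n_channels = 4, fs = 600)
  cfg$rates$rate[cfg$rates$epoch == "sustained"] <- 0.08
  trials <- generate_trial_skeleton(cfg, 50, seed = 202)
  dur <- max(trials$t_stim_on) + 3
  bg <- generate_background(cfg, dur, seed = 203)
  counts <- vapply(1:40, function(s) {
    inj <- inject_ripples(bg, cfg, trials, seed = 300 + s,
                          epochs = canonical_epochs()["sustained"])
    nrow(inj$ground_truth)
  }, numeric(1))
  lambda <- 0.08 * 0.45 * 50                 # expected events per repetition
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))
})

test_that("a session is deterministic under its seed and satisfies the data
           model", {
  cfg <- synthetic_config()
  s1 <- simulate_session(cfg, n_trials = 10, seed = 204)
  s2 <- simulate_session(cfg, n_trials = 10, seed = 204)
  expect_identical(s1$recordings$V1$data, s2$recordings$V1$data)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$trials$rt, s2$trials$rt)
  expect_s3_class(s1$trials, "trial_table")
  expect_false(anyNA(s1$recordings$V4$data))
  expect_equal(n_channels(s1$recordings$V1), 16)
  expect_equal(s1$recordings$V1$fs, 1017)
  # every ground-truth event lies inside its epoch's window
  eps <- canonical_epochs()
  for (k in seq_len(nrow(s1$ground_truth))) {
    gt <- s1$ground_truth[k, ]
    if (gt$is_partner) next                  # partners may spill over the edge
    w <- epoch_windows(s1$trials[s1$trials$trial_id == gt$trial_id, ],
                       eps[[gt$epoch]])
    expect_true(gt$t_center >= w$t_start && gt$t_center <= w$t_end)
  }
})

test_that("zero-amplitude injection leaves ground truth but no detectable
           events", {
  cfg <- synthetic_config()
  bg <- generate_background(cfg, 100, seed = 205)
  inj <- inject_bursts(bg, n_events = 12, seed = 206, amp_snr = 0)
  expect_equal(nrow(inj$ground_truth), 12)
  expect_identical(inj$rec$data, bg$data)
  ev <- detect_ripples(bipolar_rereference(inj$rec))
  expect_lte(nrow(area_events(ev)) / 100, 0.01)
})

test_that("reaction-time generator reproduces its linear model", {
  rt <- simulate_rt_trials(n_sessions = 5, trials_per_session = 2000,
                           ripple_ms = -3, session_sd_ms = 0, seed = 207)
  d <- mean(rt$rt_ms[rt$ripple == "yes"]) - mean(rt$rt_ms[rt$ripple == "no"])
  se <- 30 * sqrt(1 / sum(rt$ripple == "yes") + 1 / sum(rt$ripple == "no"))
  expect_lt(abs(d - (-3)), 3 * se)
  # full-session variant: ripple trials are defined by the sustained epoch
  cfg <- synthetic_config(rates = within(default_condition_rates(),
                                         rate <- rate * 8))
  sim <- simulate_session(cfg, n_trials = 50, seed = 208, evoked = FALSE)
  tr <- sim$trials
  gt_s <- sim$ground_truth[sim$ground_truth$epoch == "sustained", ]
  expect_setequal(tr$trial_id[tr$has_ripple], unique(gt_s$trial_id))
  expect_true(all(is.na(tr$rt[tr$outcome == "blank"])))
  expect_equal(tr$rt[tr$rt_valid],
               (tr$t_release[tr$rt_valid] - tr$t_dim[tr$rt_valid]) * 1000,
               tolerance = 1e-9)
})

test_that("spike trains have the configured baseline rate and ripple bump", {
  cfg <- synthetic_config()
  gt <- data.frame(area = "V1", channel = 5,
                   t_center = seq(5, 115, by = 5), freq_hz = 140,
                   duration_ms = 45, amplitude = 1, epoch = "sustained",
                   trial_id = 1, is_partner = FALSE)
  trials <- generate_trial_skeleton(cfg, 5, seed = 209)
  beh <- generate_trials_spikes_rts(cfg, gt, seed = 210, trials = trials,
                                    duration_s = 120)
  st <- beh$spikes[["V1_c09"]]               # channel without events
  expect_equal(length(st$spike_times) / 120, cfg$spike_baseline_hz,
               tolerance = 0.15)
  # channel 5 carries the bump: rate near event centres exceeds baseline
  st5 <- beh$spikes[["V1_c05"]]
  near <- sum(vapply(gt$t_center, function(tc)
    sum(abs(st5$spike_times - tc) < 0.02), numeric(1)))
  rate_near <- near / (length(gt$t_center) * 0.04)
  expect_gt(rate_near, cfg$spike_baseline_hz + 2)
})
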