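mini_trials <- function(n = 50, seed = 81)
  generate_trial_skeleton(synthetic_config(p_blank = 0), n, seed,
                          session_id = "s01")

test_that("epoch/condition rates reproduce the closed-form normalization", {
  trials <- mini_trials(50)
  sus <- canonical_epochs()$sustained
  win <- epoch_windows(trials, sus)
  set.seed(82)
  picks <- win[sample.int(nrow(win), 10, replace = TRUE), ]
  ev <- data.frame(session = "s01", channel = 5,
                   t_center = runif(10, picks$t_start, picks$t_end))
  tab <- epoch_condition_rates(ev, trials,
                               epochs = list(canonical_epochs()$sustained),
                               channels = 5)
  # 10 events / (50 trials x 0.45 s) pooled over the 8 condition cells
  pooled <- sum(tab$n_events) / sum(tab$n_trials * 0.45)
  expect_equal(pooled, 10 / (50 * 0.45), tolerance = 1e-12)
  expect_equal(sum(tab$n_events), 10)
  # brute-force equivalence cell by cell
  for (k in seq_len(nrow(tab))) {
    sel <- trials$cue_location == tab$cue_location[k] &
           trials$focus == tab$focus[k] & trials$stim_size == tab$stim_size[k]
    wk <- epoch_windows(trials[sel, ], sus)
    n_in <- sum(vapply(ev$t_center, function(tc)
      any(tc >= wk$t_start & tc <= wk$t_end), logical(1)))
    expect_equal(tab$rate[k], n_in / sum(wk$t_end - wk$t_start))
  }
  # electrode averaging: two electrodes with rates 0.02 and 0.06 give 0.04
  t_one <- trials[1, ]
  w1 <- epoch_windows(t_one, sus)
  ev2 <- data.frame(
    session = "s01", channel = c(rep(2, 1), rep(3, 3)),
    t_center = runif(4, w1$t_start, w1$t_end))
  tab2 <- epoch_condition_rates(ev2, t_one,
                                epochs = list(sus), channels = c(2, 3))
  expect_equal(tab2$rate, mean(c(1, 3) / 0.45), tolerance = 1e-12)
})

test_that("paired signed-rank comparison behaves at the edges and has the
           designed power", {
  # identical paired vectors: all differences zero, p = 1
  tbl <- simulate_rate_table(n_sessions = 6, size_effect = 0, att_effect = 0,
                             focus_effect = 0, noise_sd = 0, session_sd = 0.01,
                             seed = 83)
  res <- compare_rates_paired(tbl, "stim_size")
  expect_equal(res$p.value, 1)
  expect_equal(res$n, 0)
  # exact small-n distribution matches enumeration
  set.seed(84)
  x <- rnorm(5); y <- x + rnorm(5, 0.5)
  tbl2 <- data.frame(session = rep(sprintf("s%d", 1:5), 2),
                     epoch = "sustained",
                     stim_size = rep(c("large", "small"), each = 5),
                     rate = c(x, y))
  res2 <- compare_rates_paired(tbl2, "stim_size")
  expect_equal(res2$p.value, oracle_signrank_p(y - x), tolerance = 1e-12)
  # recorded-study effect scale (0.09 vs 0.04, session SD 0.02, 40 sessions):
  # detected in at least 95% of 200 replicates
  hits <- 0
  for (r in 1:200) {
    set.seed(r)
    small <- rnorm(40, 0.09, 0.02)
    large <- rnorm(40, 0.04, 0.02)
    t3 <- data.frame(session = rep(sprintf("s%02d", 1:40), 2),
                     epoch = "sustained",
                     stim_size = rep(c("large", "small"), each = 40),
                     rate = c(large, small))
    hits <- hits + (compare_rates_paired(t3, "stim_size")$p.value < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("repeated-measures ANOVA matches the per-session contrast oracle", {
  tbl <- simulate_rate_table(n_sessions = 6, seed = 85)
  a <- rm_anova3(tbl)
  expect_setequal(
    a$effect,
    c("cue_location", "focus", "stim_size", "cue_location:focus",
      "cue_location:stim_size", "focus:stim_size",
      "cue_location:focus:stim_size"))
  expect_equal(attr(a, "n_sessions"), 6)
  # each 2-level within-subject effect's F equals the squared paired-t on
  # the per-session contrast scores
  contrast_F <- function(score) {
    tt <- t.test(score)
    unname(tt$statistic)^2
  }
  ms <- aggregate(rate ~ session + stim_size, tbl, mean)
  d_size <- ms$rate[ms$stim_size == "small"] - ms$rate[ms$stim_size == "large"]
  expect_equal(a$F[a$effect == "stim_size"], contrast_F(d_size),
               tolerance = 1e-8)
  m2 <- aggregate(rate ~ session + cue_location + stim_size, tbl, mean)
  dd <- with(m2, rate[cue_location == "RF" & stim_size == "small"] -
                 rate[cue_location == "RF" & stim_size == "large"] -
                 rate[cue_location == "away" & stim_size == "small"] +
                 rate[cue_location == "away" & stim_size == "large"])
  expect_equal(a$F[a$effect == "cue_location:stim_size"], contrast_F(dd),
               tolerance = 1e-8)
  # incomplete sessions are excluded listwise
  extra <- simulate_rate_table(n_sessions = 1, seed = 86)
  extra$session <- "s99"
  tbl_inc <- rbind(tbl, extra)
  tbl_inc <- tbl_inc[-(nrow(tbl_inc)), ]    # drop one cell of the new session
  expect_message(a2 <- rm_anova3(tbl_inc), "incomplete")
  expect_equal(attr(a2, "n_sessions"), 6)
  expect_error(rm_anova3(tbl[tbl$session %in% c("s01", "s02"), ]), "3")
})

test_that("post hoc signed-rank FDR equals an independent BH step-up", {
  set.seed(87)
  contrasts <- lapply(1:6, function(k)
    list(x = rnorm(12), y = rnorm(12, mean = 0.3 * (k %% 2))))
  names(contrasts) <- paste0("c", 1:6)
  res <- posthoc_signrank_fdr(contrasts)
  expect_equal(res$p_adj, oracle_bh(res$p_raw), tolerance = 1e-12)
  one <- posthoc_signrank_fdr(contrasts[1])
  expect_equal(one$p_adj, one$p_raw)
})

test_that("cross-correlogram localizes an imposed lag and is symmetric for
           identical trains", {
  trials <- mini_trials(60, seed = 88)
  ea <- poisson_epoch_events(trials, canonical_epochs()$sustained, 1.2, 89)
  eb <- data.frame(t_center = ea$t_center + 0.020)
  xc <- cross_area_correlogram(ea, eb, trials, n_shuffles = 60)
  expect_equal(xc$lags[which.max(xc$corrected)], 20)
  expect_gt(xc$auc_lead, xc$auc_lag)
  expect_equal(xc$auc_lead + xc$auc_lag, sum(xc$corrected))
  xi <- cross_area_correlogram(ea, ea, trials, n_shuffles = 60)
  expect_equal(xi$lags[which.max(xi$corrected)], 0)
  expect_lt(abs(xi$auc_lead - xi$auc_lag),
            0.1 * sum(abs(xi$corrected)) + 1e-9)
  w1 <- epoch_windows(trials[1, ], canonical_epochs()$sustained)
  one <- data.frame(t_center = w1$t_start + 0.1)
  expect_error(cross_area_correlogram(one, one, trials[1, ],
                                      n_shuffles = 10),
               "fewer than 2 trials")
})

test_that("per-pair AUC asymmetry test detects a consistent lead", {
  trials <- mini_trials(60, seed = 90)
  ea <- poisson_epoch_events(trials, canonical_epochs()$sustained, 1.5, 91)
  ea$channel <- sample(2:4, nrow(ea), replace = TRUE)
  eb <- data.frame(t_center = ea$t_center + 0.022,
                   channel = sample(2:4, nrow(ea), replace = TRUE))
  xc <- cross_area_correlogram(ea, eb, trials, n_shuffles = 40,
                               pair_test = TRUE)
  expect_true(length(xc$pair_auc_diff) > 1)
  expect_gt(mean(xc$pair_auc_diff > 0), 0.5)
  expect_lt(xc$pair_test$p.value, 0.05)
})

test_that("cooccurrence probability matches edge cases and the Poisson
           prediction", {
  trials <- mini_trials(200, seed = 92)
  sus <- canonical_epochs()$sustained
  ea <- poisson_epoch_events(trials, sus, 1.0, 93)
  expect_equal(cooccurrence_probability(ea, ea, trials, sus)$probability, 1)
  none <- data.frame(t_center = numeric())
  expect_equal(cooccurrence_probability(ea, none, trials, sus)$probability, 0)
  # independent Poisson partner: P(B in trial) = 1 - exp(-lambda * T)
  lam_b <- 2.0
  eb <- poisson_epoch_events(trials, sus, lam_b, 94)
  got <- cooccurrence_probability(ea, eb, trials, sus)$probability
  expect_equal(got, 1 - exp(-lam_b * 0.45), tolerance = 0.12)
})

test_that("ripple-locked spike rate shows the injected bump against the
           matched control", {
  cfg <- synthetic_config(rates = within(default_condition_rates(),
                                         rate <- rate * 8))
  sim <- simulate_session(cfg, n_trials = 60, seed = 95, evoked = FALSE)
  gt <- sim$ground_truth
  gt <- gt[gt$area == "V1" & gt$epoch == "sustained", ]
  v1_spikes <- sim$spikes[grep("^V1", names(sim$spikes))]
  names(v1_spikes) <- NULL
  psth <- ripple_locked_spike_rate(v1_spikes, gt, sim$trials,
                                   window_ms = 200, bin_ms = 20)
  expect_gt(psth$n_events, 5)
  mid <- which.min(abs(psth$lags_ms))
  nb <- length(psth$lags_ms)
  edge <- c(1, 2, nb - 1, nb)        # bins far outside the 15-ms bump
  bump <- psth$ripple_rate[mid] - psth$control_rate[mid]
  expect_gt(bump, 3)                 # injected gain is +8 Hz at lag 0
  edge_diff <- mean(psth$ripple_rate[edge] - psth$control_rate[edge])
  expect_gt(bump, edge_diff)         # elevation is ripple-locked, not global
  expect_lt(abs(edge_diff), 10)      # Monte-Carlo SE ~ 4-5 Hz at this scale
  # spikes independent of events: both PSTHs flat and equal within noise
  ind <- gt
  set.seed(96)
  ind$channel <- sample(setdiff(2:15, unique(gt$channel)), nrow(gt), TRUE)
  psth0 <- ripple_locked_spike_rate(v1_spikes, ind, sim$trials,
                                    window_ms = 200, bin_ms = 20)
  expect_lt(abs(psth0$ripple_rate[mid] - psth0$control_rate[mid]), 8)
})

test_that("mixed model recovers injected effects and degenerates to OLS", {
  rt <- simulate_rt_trials(n_sessions = 8, trials_per_session = 250,
                           ripple_ms = -3, seed = 97)
  mr <- fit_mixed_model(rt, "rt_ms")
  co <- mr$coefficients
  b_rip <- co$estimate[co$term == "rippleyes"]
  se_rip <- co$se[co$term == "rippleyes"]
  expect_lt(abs(b_rip - (-3)), 2 * se_rip + 1)
  expect_gt(mr$ranef_var, 0)
  expect_setequal(mr$anova$effect,
                  c("cue_location", "ripple", "focus", "stim_size"))
  # null generator: coefficients within 2 SE of zero
  rt0 <- simulate_rt_trials(n_sessions = 6, trials_per_session = 200,
                            ripple_ms = 0, att_ms = 0, size_ms = 0,
                            focus_ms = 0, seed = 98)
  m0 <- fit_mixed_model(rt0, "rt_ms")
  c0 <- m0$coefficients
  for (term in c("rippleyes", "cue_locationRF", "focuswide",
                 "stim_sizesmall")) {
    est <- c0$estimate[c0$term == term]
    expect_lt(abs(est), 3 * c0$se[c0$term == term])
  }
  # pooled fit equals closed-form OLS
  mp <- fit_mixed_model(rt, "rt_ms", random = FALSE)
  X <- model.matrix(~ relevel(factor(cue_location), "away") +
                      relevel(factor(ripple), "no") +
                      relevel(factor(focus), "narrow") +
                      relevel(factor(stim_size), "large"), data = rt)
  beta <- oracle_ols(X, rt$rt_ms)
  expect_equal(unname(mp$coefficients$estimate), beta, tolerance = 1e-8)
})

test_that("spike-triggered average exposes injected spike leakage", {
  fs <- 1017
  set.seed(99)
  sig <- rnorm(60 * fs)
  spikes <- sort(runif(400, 1, 59))
  leak <- function(x, times) {
    for (t_s in times) {
      i <- round(t_s * fs) + 1
      x[i:(i + 3)] <- x[i:(i + 3)] + c(-6, 9, -4, 1)
    }
    x
  }
  sta_clean <- spike_triggered_average(sig, fs, spikes)
  sta_leak <- spike_triggered_average(leak(sig, spikes), fs, spikes)
  mid <- which.min(abs(sta_leak$lags_ms))
  expect_gt(max(abs(sta_leak$sta[mid + 0:3])), 5)
  expect_lt(max(abs(sta_clean$sta)), 1)
  expect_equal(sta_leak$n_spikes, 400)
})
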