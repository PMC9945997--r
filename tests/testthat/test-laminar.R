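test_that("CSD is the negative second spatial difference", {
  fs <- 100
  n <- 50
  # linear depth gradient: exactly zero CSD
  lin <- outer(1:8, rep(1, n)) * 0.5   # binary-exact values
  rec <- laminar_recording(lin, fs = fs, contact_spacing = 150)
  csd <- compute_csd(rec)
  expect_equal(dim(csd$csd), c(6, n))       # edges lose their estimate
  expect_true(all(csd$csd == 0))
  # Gaussian-in-depth potential: extremum at the peak contact
  g <- exp(-((1:16) - 8)^2 / 8)
  m <- outer(-g, rep(1, n)) * 40
  csd2 <- compute_csd(laminar_recording(m, fs = fs, contact_spacing = 150))
  sink_contact <- csd2$contact_ids[which.min(csd2$csd[, 1])]
  expect_equal(sink_contact, 8)
  # 1/h^2 scaling: halving the spacing quadruples the magnitude
  csd_h <- compute_csd(laminar_recording(m, fs = fs, contact_spacing = 75))
  expect_equal(csd_h$csd, 4 * csd2$csd)
  # Vaknin edge replication keeps every contact
  csd_v <- compute_csd(laminar_recording(m, fs = fs, contact_spacing = 150),
                       vaknin = TRUE)
  expect_equal(nrow(csd_v$csd), 16)
})

test_that("response latency finds the injected onset and respects
           monotonicity", {
  cfg <- synthetic_config()
  sim <- simulate_session(cfg, n_trials = 40, seed = 71)
  lat <- response_latency(sim$recordings$V1, sim$trials)
  true_lat <- attr(sim$recordings$V1, "true_latency_ms")
  expect_lt(abs(lat$latency_ms[8] - true_lat[8]), 5)
  # onset gradient: contacts nearer the input layer respond earlier
  expect_lt(lat$latency_ms[8], lat$latency_ms[12])
  expect_lt(lat$latency_ms[8], lat$latency_ms[4])
  # earlier injected onset yields a smaller measured latency
  cfg2 <- synthetic_config(latency_input_ms = 60)
  sim2 <- simulate_session(cfg2, n_trials = 40, seed = 71)
  lat2 <- response_latency(sim2$recordings$V1, sim2$trials)
  expect_lt(lat$latency_ms[8], lat2$latency_ms[8])
  # flat signal: no crossing, latency absent
  flat <- sim$recordings$V1
  flat$data <- matrix(0, nrow(flat$data), ncol(flat$data))
  latf <- response_latency(flat, sim$trials)
  expect_true(all(is.na(latf$latency_ms)))
  expect_error(response_latency(sim$recordings$V1, sim$trials[1:5, ]),
               "20")
})

test_that("layer assignment follows sink + latency and supports overrides", {
  # constructed profile: sink block at contacts 7-9, fastest latency at 8
  g <- exp(-((1:16) - 8)^2 / 8)
  m <- outer(-g, rep(1, 60)) * 40
  m[, 1:20] <- 0                            # pre-anchor baseline
  rec <- laminar_recording(m, fs = 100, contact_spacing = 150, t0 = -0.2)
  csd <- compute_csd(rec)
  lats <- data.frame(contact_id = 1:16,
                     latency_ms = 40 + 4 * abs((1:16) - 8))
  la <- assign_layers(csd, lats, all_contact_ids = 1:16)
  expect_equal(la$labels$contact_id[la$labels$label == "input"], 7:9)
  expect_equal(la$labels$contact_id[la$labels$label == "superficial"], 2:6)
  expect_equal(la$labels$contact_id[la$labels$label == "deep"], 10:15)
  expect_equal(la$labels$label[c(1, 16)], c("excluded", "excluded"))
  expect_equal(unname(la$n_contacts["input"]), 3L)
  # sink and latency disagreeing by > 2 contacts is ambiguous
  lats_far <- data.frame(contact_id = 1:16,
                         latency_ms = 40 + 4 * abs((1:16) - 12))
  expect_error(assign_layers(csd, lats_far, all_contact_ids = 1:16),
               "ambiguous")
  # an override short-circuits everything
  ov <- data.frame(contact_id = 1:16,
                   label = c("excluded", rep("superficial", 5),
                             rep("input", 4), rep("deep", 5), "excluded"))
  lo <- assign_layers(csd, lats_far, override = ov)
  expect_equal(lo$labels$label, ov$label)
})

test_that("layer assignment recovers the generator's ground truth", {
  cfg <- synthetic_config()
  sim <- simulate_session(cfg, n_trials = 60, seed = 72)
  avg <- trial_average(sim$recordings$V1, sim$trials,
                       pre_s = 0.1, post_s = 0.25)
  lat <- response_latency(sim$recordings$V1, sim$trials)
  la <- assign_layers(compute_csd(avg), lat, all_contact_ids = 1:16)
  truth <- attr(sim$recordings$V1, "true_input_contacts")
  got <- la$labels$contact_id[la$labels$label == "input"]
  expect_lte(abs(min(got) - min(truth)), 1)
  expect_lte(abs(max(got) - max(truth)), 1)
  expect_true(which.min(lat$latency_ms) %in% truth)
})

test_that("layer ripple rates are contact-count-normalized", {
  labels <- data.frame(contact_id = 1:16,
                       label = c("excluded", rep("superficial", 5),
                                 rep("input", 3), rep("deep", 6), "excluded"))
  layers <- assign_layers(NULL, NULL, override = labels)
  cfg <- synthetic_config()
  trials <- generate_trial_skeleton(cfg, 50, seed = 73)
  sus <- canonical_epochs()$sustained
  win <- epoch_windows(trials, sus)
  # 12 events on the 3 input contacts inside sustained windows
  set.seed(74)
  ev <- data.frame(
    channel = rep(7:9, 4),
    t_center = vapply(1:12, function(k) {
      w <- win[sample.int(nrow(win), 1), ]
      runif(1, w$t_start, w$t_end)
    }, numeric(1)))
  rr <- layer_ripple_rates(ev, layers, trials, sus)
  expect_equal(rr$rate_per_contact[rr$layer == "input"],
               (12 / (50 * 0.45)) / 3, tolerance = 1e-12)
  expect_equal(rr$rate_per_contact[rr$layer == "deep"], 0)
  # doubling the contact count at fixed events halves the normalized rate
  labels6 <- labels
  labels6$label[c(2, 3, 4)] <- "input"      # 6 input contacts
  layers6 <- assign_layers(NULL, NULL, override = labels6)
  rr6 <- layer_ripple_rates(ev, layers6, trials, sus)
  expect_equal(rr6$rate_per_contact[rr6$layer == "input"],
               rr$rate_per_contact[rr$layer == "input"] / 2)
})
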