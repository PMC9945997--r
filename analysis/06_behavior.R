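#!/usr/bin/env Rscript
# Behavioural and spiking correlates of ripples: the ripple-locked spike
# rate against condition/time-matched ripple-free control trials, and the
# session-random-intercept mixed model of reaction times.

library(ripplepipe)
dir.create("results", showWarnings = FALSE)

## spiking at ripple time (elevated rate so enough events exist)
cfg <- synthetic_config(rates = within(default_condition_rates(),
                                       rate <- rate * 8))
sim <- simulate_session(cfg, n_trials = 80, seed = 901, evoked = FALSE)
gt <- sim$ground_truth
gt <- gt[gt$area == "V1" & gt$epoch == "sustained", ]
v1_units <- unname(sim$spikes[grep("^V1", names(sim$spikes))])
psth <- ripple_locked_spike_rate(v1_units, gt, sim$trials,
                                 window_ms = 200, bin_ms = 10)
mid <- which.min(abs(psth$lags_ms))
cat(sprintf(
  "spike rate at ripple time: %.1f Hz vs matched control %.1f Hz (%d events)\n",
  psth$ripple_rate[mid], psth$control_rate[mid], psth$n_events))
write.csv(data.frame(lag_ms = psth$lags_ms,
                     ripple_hz = psth$ripple_rate,
                     ripple_sem = psth$ripple_sem,
                     control_hz = psth$control_rate,
                     control_sem = psth$control_sem),
          "results/psth.csv", row.names = FALSE)

## reaction-time mixed model at the recorded design scale
cfg0 <- synthetic_config()
rt <- simulate_rt_trials(n_sessions = 43, trials_per_session = 350,
                         ripple_ms = cfg0$rt_ripple_ms,
                         att_ms = cfg0$rt_att_ms, size_ms = cfg0$rt_size_ms,
                         session_sd_ms = cfg0$rt_session_sd_ms,
                         noise_sd_ms = cfg0$rt_noise_sd_ms, seed = 902)
cat(sprintf("mean RT: %.2f ms with ripples vs %.2f ms without\n",
            mean(rt$rt_ms[rt$ripple == "yes"]),
            mean(rt$rt_ms[rt$ripple == "no"])))
mm <- fit_mixed_model(rt, "rt_ms")
print(mm$coefficients, digits = 4)
print(mm$anova, digits = 3)
jsonlite::write_json(list(coefficients = mm$coefficients,
                          anova = mm$anova,
                          session_intercept_var = mm$ranef_var),
                     "results/rt_model.json", auto_unbox = TRUE, digits = NA)
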