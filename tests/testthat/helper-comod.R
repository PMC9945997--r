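# paired recordings whose only across-event covariation is a 150-Hz burst
# (trigger) driving a 60-Hz burst (target) of proportional amplitude
make_coupled <- function(seed, n_ev, coupled = TRUE, dur_s = NULL) {
  fs <- 1017
  if (is.null(dur_s)) dur_s <- n_ev * 0.35 + 2
  cfg <- synthetic_config(n_channels = 3)
  trig <- generate_background(cfg, dur_s, seed = seed)
  targ <- generate_background(cfg, dur_s, seed = seed + 1)
  tc <- seq(1, dur_s - 1, length.out = n_ev)
  set.seed(seed + 2)
  amp <- runif(n_ev, 0.5, 1.5) * 30
  if (coupled) {
    t1 <- (seq_len(ncol(trig$data)) - 1) / fs
    for (k in seq_len(n_ev)) {
      idx <- which(abs(t1 - tc[k]) < 0.06)
      tt <- t1[idx] - tc[k]
      env <- exp(-tt^2 / (2 * 0.025^2))
      trig$data[1, idx] <- trig$data[1, idx] +
        amp[k] * cos(2 * pi * 150 * tt) * env
      targ$data[1, idx] <- targ$data[1, idx] +
        amp[k] * cos(2 * pi * 60 * tt) * env
    }
  }
  list(trig = trig, targ = targ, times = tc)
}
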