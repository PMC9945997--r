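#' Default condition-dependent ripple rates
#'
#' Rates (events/s, per area) used by the synthetic generator: flat 0.01 in
#' the precue and postcue epochs, and in the sustained epoch an additive
#' model around 0.065 events/s with a +/-0.025 stimulus-size effect
#' (small > large), a +/-0.025 attentional-cue effect (cue RF > away) and a
#' +/-0.005 focus effect (wide > narrow), matching the magnitudes reported
#' for extrastriate recordings (small vs large 0.09 vs 0.04 events/s; cue RF
#' vs away 0.09 vs 0.04 events/s in the sustained period).
#'
#' @return data.frame with `epoch`, `cue_location`, `focus`, `stim_size`,
#'   `rate`.
#' @export
default_condition_rates <- function() {
  grid <- expand.grid(cue_location = c("away", "RF"),
                      focus = c("narrow", "wide"),
                      stim_size = c("large", "small"),
                      stringsAsFactors = FALSE)
  out <- NULL
  for (ep in c("precue", "postcue", "sustained")) {
    g <- grid
    g$epoch <- ep
    g$rate <- if (ep == "sustained")
      0.065 + 0.025 * ifelse(g$stim_size == "small", 1, -1) +
        0.025 * ifelse(g$cue_location == "RF", 1, -1) +
        0.005 * ifelse(g$focus == "wide", 1, -1)
    else 0.01
    out <- rbind(out, g)
  }
  out[, c("epoch", "cue_location", "focus", "stim_size", "rate")]
}

#' Synthetic session configuration
#'
#' Bundles every parameter of the synthetic generator. Defaults reproduce
#' the recorded sessions' study conditions: 16 contacts per area at 150-um
#' spacing sampled at 1017 Hz, 1/f background LFP, ripple bursts of
#' 100-180 Hz lasting 30-60 ms at 6x the rereferenced ripple-band RMS,
#' condition-dependent Poisson rates (see [default_condition_rates()]),
#' V1-to-V4 partner events at a ~22-ms lag with 0.1 cooccurrence, an
#' input-layer evoked response/sink for the laminar analyses, 22-Hz baseline
#' spiking with a ripple-locked +8 Hz bump, and reaction times around 311 ms
#' reduced by ~2.4 ms on ripple trials.
#'
#' @param n_channels contacts per area.
#' @param fs sampling rate, Hz.
#' @param contact_spacing um.
#' @param background_alpha 1/f exponent of the background LFP.
#' @param background_rms background RMS, uV.
#' @param common_frac variance fraction of the depth-shared component.
#' @param ripple_freq_hz centre-frequency range of injected bursts, Hz.
#' @param ripple_dur_ms duration range of injected bursts, ms.
#' @param ripple_amp_snr burst amplitude in multiples of the rereferenced
#'   ripple-band RMS (calibrated so peak z reliably exceeds the confirmation
#'   threshold).
#' @param rates condition-rate table (see [default_condition_rates()]).
#' @param lag_mean_ms,lag_sd_ms V1-to-V4 partner-event lag, ms.
#' @param co_occurrence probability that a V1 event spawns a V4 partner.
#' @param input_center,input_sigma depth centre/width (contact units) of the
#'   evoked input-layer sink.
#' @param latency_input_ms evoked-response onset at the input layer, ms.
#' @param latency_slope_ms onset increase per contact away from the input
#'   layer, ms.
#' @param evoked_amp slow evoked-potential amplitude, uV.
#' @param mua_amp amplitude scale of the brief high-frequency (multiunit-like)
#'   onset burst, uV.
#' @param spike_baseline_hz,spike_ripple_gain_hz,spike_sigma_ms spiking
#'   model: baseline rate, ripple-locked Gaussian gain and width.
#' @param rt_base_ms,rt_ripple_ms,rt_att_ms,rt_size_ms,rt_focus_ms,
#'   rt_session_sd_ms,rt_noise_sd_ms reaction-time model: baseline, additive
#'   effects of ripple occurrence / cue RF / small stimulus / wide focus,
#'   session random-intercept SD and trial noise SD.
#' @param fix_to_cue_s,cue_dur_s,delay_s,dim_range_s,iti_s trial timing.
#' @param p_blank fraction of blank trials.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 16, fs = 1017,
                             contact_spacing = 150,
                             background_alpha = 1, background_rms = 30,
                             common_frac = 0.6,
                             ripple_freq_hz = c(100, 180),
                             ripple_dur_ms = c(30, 60),
                             ripple_amp_snr = 6,
                             rates = default_condition_rates(),
                             lag_mean_ms = 22, lag_sd_ms = 5,
                             co_occurrence = 0.1,
                             input_center = 8, input_sigma = 2,
                             latency_input_ms = 40, latency_slope_ms = 4,
                             evoked_amp = 250, mua_amp = 25,
                             spike_baseline_hz = 22,
                             spike_ripple_gain_hz = 8, spike_sigma_ms = 15,
                             rt_base_ms = 311, rt_ripple_ms = -2.4,
                             rt_att_ms = -2, rt_size_ms = -2,
                             rt_focus_ms = 0, rt_session_sd_ms = 10,
                             rt_noise_sd_ms = 30,
                             fix_to_cue_s = 0.35, cue_dur_s = 0.25,
                             delay_s = 1.0, dim_range_s = c(0.75, 1.25),
                             iti_s = 0.6, p_blank = 0.05) {
  stopifnot(all(rates$rate >= 0), ripple_dur_ms[1] < ripple_dur_ms[2])
  structure(as.list(environment()), class = "synthetic_config")
}

# spectral synthesis of 1/f^alpha noise with unit SD
.pink_noise <- function(n, fs, alpha) {
  nfft <- stats::nextn(n, 2)
  nf <- nfft / 2
  f <- (1:nf) * fs / nfft
  amp <- f^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- c(0, half[1:(nf - 1)], Re(half[nf]), Conj(rev(half[1:(nf - 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n]
  (x - mean(x)) / stats::sd(x)
}

#' Generate 1/f background LFP for one probe
#'
#' Each contact is a mix of a depth-shared 1/f component (with a smooth gain
#' gradient across depth, so bipolar rereferencing removes most but not all
#' of it) and an independent 1/f component, scaled to the configured RMS.
#'
#' @param cfg a [synthetic_config()].
#' @param duration_s recording length, seconds.
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @param area,session_id labels for the recording.
#' @param t0 session time of the first sample.
#' @return a [laminar_recording()].
#' @export
generate_background <- function(cfg, duration_s, seed, area = "V1",
                                session_id = "synthetic", t0 = 0) {
  set.seed(seed)
  n <- round(duration_s * cfg$fs)
  common <- .pink_noise(n, cfg$fs, cfg$background_alpha)
  gain <- 0.8 + 0.4 * (seq_len(cfg$n_channels) - 1) / (cfg$n_channels - 1)
  data <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    indep <- .pink_noise(n, cfg$fs, cfg$background_alpha)
    x <- sqrt(cfg$common_frac) * gain[ch] * common +
      sqrt(1 - cfg$common_frac) * indep
    data[ch, ] <- x / stats::sd(x) * cfg$background_rms
  }
  laminar_recording(data, fs = cfg$fs, area = area, session_id = session_id,
                    contact_spacing = cfg$contact_spacing, t0 = t0)
}

#' Generate the trial skeleton of a session
#'
#' Balanced random ordering of the eight condition combinations with the
#' canonical timing: fixation, cue onset after `fix_to_cue_s`, 250-ms cue,
#' 1000-ms delay, stimulus onset, dimming after `dim_range_s`. Reaction
#' times and `t_release` are filled in later by
#' [generate_trials_spikes_rts()]. A small fraction of trials are blanks
#' (no dimming, no RT).
#'
#' @param cfg a [synthetic_config()].
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @param session_id session label.
#' @param t_start session time of the first fixation, seconds.
#' @return a `trial_table`.
#' @export
generate_trial_skeleton <- function(cfg, n_trials, seed,
                                    session_id = "synthetic", t_start = 2) {
  set.seed(seed)
  combos <- expand.grid(cue_location = c("away", "RF"),
                        focus = c("narrow", "wide"),
                        stim_size = c("large", "small"),
                        stringsAsFactors = FALSE)
  idx <- rep(seq_len(8), length.out = n_trials)
  idx <- sample(idx)
  blank <- stats::runif(n_trials) < cfg$p_blank
  t_fix <- numeric(n_trials)
  t_dim <- numeric(n_trials)
  cur <- t_start
  for (k in seq_len(n_trials)) {
    t_fix[k] <- cur
    stim_on <- cur + cfg$fix_to_cue_s + cfg$cue_dur_s + cfg$delay_s
    t_dim[k] <- if (blank[k]) NA else
      stim_on + stats::runif(1, cfg$dim_range_s[1], cfg$dim_range_s[2])
    cur <- stim_on + cfg$dim_range_s[2] + 0.5 + cfg$iti_s
  }
  df <- data.frame(
    trial_id = seq_len(n_trials), session_id = session_id,
    cue_location = combos$cue_location[idx], focus = combos$focus[idx],
    stim_size = combos$stim_size[idx],
    t_fix = t_fix, t_cue_on = t_fix + cfg$fix_to_cue_s,
    t_cue_off = t_fix + cfg$fix_to_cue_s + cfg$cue_dur_s,
    t_stim_on = t_fix + cfg$fix_to_cue_s + cfg$cue_dur_s + cfg$delay_s,
    t_dim = t_dim, t_release = NA_real_,
    outcome = ifelse(blank, "blank", "hit"), stringsAsFactors = FALSE)
  load_trials(df)
}

#' Inject ripple-like bursts at given or random times
#'
#' Low-level injector used by [inject_ripples()] and directly useful for
#' detector validation at arbitrary event density: adds Gaussian-enveloped
#' sinusoids on randomly chosen interior contacts. Amplitude is expressed as
#' a multiple of the ripple-band RMS of the bipolar-rereferenced recording
#' (`amp_snr = 0` injects nothing visible but still returns ground truth).
#'
#' @param rec a [laminar_recording()].
#' @param n_events number of bursts (ignored when `times` given).
#' @param seed RNG seed.
#' @param times optional burst centre times (s); default: uniform over the
#'   recording with 0.5-s margins and >= 0.25-s separation.
#' @param freq_range,dur_range_ms,amp_snr burst parameters
#'   (see [synthetic_config()]).
#' @return list: `rec` (with bursts added), `ground_truth`.
#' @export
inject_bursts <- function(rec, n_events, seed, times = NULL,
                          freq_range = c(100, 180),
                          dur_range_ms = c(30, 60), amp_snr = 6) {
  set.seed(seed)
  if (is.null(times)) {
    span <- ncol(rec$data) / rec$fs
    cand <- sort(stats::runif(n_events * 4, 0.5, span - 0.5)) + rec$t0
    times <- cand[c(TRUE, diff(cand) > 0.25)]
    if (length(times) > n_events)
      times <- sort(sample(times, n_events))
  }
  rr <- bipolar_rereference(rec)
  band_rms <- mean(apply(rr$data[c(1, nrow(rr$data) %/% 2, nrow(rr$data)), ,
                                 drop = FALSE], 1, function(ch)
    stats::sd(fir_bandpass_zerophase(ch, rec$fs, c(80, 250)))))
  gt <- NULL
  for (t_c in times) {
    ch <- sample(2:(nrow(rec$data) - 1), 1)
    freq <- stats::runif(1, freq_range[1], freq_range[2])
    dur <- stats::runif(1, dur_range_ms[1], dur_range_ms[2]) / 1000
    amp <- amp_snr * band_rms
    phase <- stats::runif(1, 0, 2 * pi)
    half <- dur * 1.6
    i0 <- max(1L, round((t_c - half - rec$t0) * rec$fs))
    i1 <- min(ncol(rec$data), round((t_c + half - rec$t0) * rec$fs))
    if (i1 <= i0) next
    rel <- t_c - (rec$t0 + (i0 - 1) / rec$fs)
    rec$data[ch, i0:i1] <- rec$data[ch, i0:i1] +
      .gauss_burst(i1 - i0 + 1, rec$fs, rel, freq, dur, amp, phase)
    gt <- rbind(gt, data.frame(area = rec$area, channel = rec$contact_ids[ch],
                               t_center = t_c, freq_hz = freq,
                               duration_ms = dur * 1000, amplitude = amp))
  }
  list(rec = rec, ground_truth = gt)
}

.gauss_burst <- function(n_samp, fs, t_center_rel, freq, dur_s, amp, phase) {
  tt <- (seq_len(n_samp) - 1) / fs - t_center_rel
  sigma <- dur_s / 2.5
  amp * exp(-tt^2 / (2 * sigma^2)) * sin(2 * pi * freq * tt + phase)
}

#' Sample ripple event times from the condition-rate model
#'
#' Draws Poisson event counts per trial, epoch and condition cell at the
#' configured rates, with uniform placement inside the epoch window (40-ms
#' margins so a burst fits), random centre frequency and duration, and --
#' when two areas are requested -- a second-area partner for each first-area
#' event with probability `co_occurrence` at a Normal(`lag_mean_ms`,
#' `lag_sd_ms`) lag. This is the pure event model; [inject_ripples()] adds
#' the corresponding bursts to recordings.
#'
#' @param cfg a [synthetic_config()].
#' @param trials a `trial_table`.
#' @param seed RNG seed.
#' @param areas one or two area labels (lead area first).
#' @param epochs named epoch list (default [canonical_epochs()]).
#' @return data.frame: `area`, `t_center`, `freq_hz`, `duration_ms`,
#'   `epoch`, `trial_id`, `is_partner`.
#' @export
sample_ripple_events <- function(cfg, trials, seed, areas = c("V1", "V4"),
                                 epochs = canonical_epochs()) {
  set.seed(seed)
  gt <- NULL
  draw <- function(area, t_center, epoch, trial_id, is_partner)
    data.frame(area = area, t_center = t_center,
               freq_hz = stats::runif(1, cfg$ripple_freq_hz[1],
                                      cfg$ripple_freq_hz[2]),
               duration_ms = stats::runif(1, cfg$ripple_dur_ms[1],
                                          cfg$ripple_dur_ms[2]),
               epoch = epoch, trial_id = trial_id, is_partner = is_partner)
  for (ep in epochs) {
    win <- epoch_windows(trials, ep)
    for (k in seq_len(nrow(win))) {
      tr <- trials[trials$trial_id == win$trial_id[k], , drop = FALSE]
      rate <- cfg$rates$rate[
        cfg$rates$epoch == ep$name &
        cfg$rates$cue_location == as.character(tr$cue_location) &
        cfg$rates$focus == as.character(tr$focus) &
        cfg$rates$stim_size == as.character(tr$stim_size)]
      if (!length(rate) || rate <= 0) next
      n_ev <- stats::rpois(1, rate * (win$t_end[k] - win$t_start[k]))
      if (!n_ev) next
      for (t_c in stats::runif(n_ev, win$t_start[k] + 0.04,
                               win$t_end[k] - 0.04)) {
        gt <- rbind(gt, draw(areas[1], t_c, ep$name, win$trial_id[k], FALSE))
        if (length(areas) > 1 && stats::runif(1) < cfg$co_occurrence) {
          lag_s <- stats::rnorm(1, cfg$lag_mean_ms, cfg$lag_sd_ms) / 1000
          gt <- rbind(gt, draw(areas[2], t_c + lag_s, ep$name,
                               win$trial_id[k], TRUE))
        }
      }
    }
  }
  if (is.null(gt))
    gt <- data.frame(area = character(), t_center = numeric(),
                     freq_hz = numeric(), duration_ms = numeric(),
                     epoch = character(), trial_id = integer(),
                     is_partner = logical())
  gt
}

#' Inject ripple bursts with ground truth
#'
#' Samples event times from the condition-rate model
#' (see [sample_ripple_events()]) and adds each event as a
#' Gaussian-enveloped sinusoid on one randomly chosen interior contact of
#' the corresponding recording. Burst amplitude is `ripple_amp_snr` times
#' the ripple-band RMS of the bipolar-rereferenced background of the same
#' recording.
#'
#' @param recs a [laminar_recording()] or a list of one or two (lead area
#'   first).
#' @param cfg a [synthetic_config()].
#' @param trials a `trial_table`.
#' @param seed RNG seed.
#' @param epochs named epoch list (default [canonical_epochs()]).
#' @return list: `recs` (with bursts added), `ground_truth` (data.frame:
#'   `area`, `channel`, `t_center`, `freq_hz`, `duration_ms`, `amplitude`,
#'   `epoch`, `trial_id`, `is_partner`).
#' @export
inject_ripples <- function(recs, cfg, trials, seed,
                           epochs = canonical_epochs()) {
  if (inherits(recs, "laminar_recording")) recs <- list(recs)
  gt <- sample_ripple_events(cfg, trials, seed,
                             areas = vapply(recs, `[[`, "", "area"),
                             epochs = epochs)
  band_rms <- vapply(recs, function(r) {
    rr <- bipolar_rereference(r)
    mean(apply(rr$data[c(1, nrow(rr$data) %/% 2, nrow(rr$data)), ,
                       drop = FALSE], 1, function(ch)
      stats::sd(fir_bandpass_zerophase(ch, r$fs, c(80, 250)))))
  }, numeric(1))
  if (nrow(gt) == 0) {
    gt$channel <- integer(0)
    gt$amplitude <- numeric(0)
    return(list(recs = recs,
                ground_truth = gt[, c("area", "channel", "t_center",
                                      "freq_hz", "duration_ms", "amplitude",
                                      "epoch", "trial_id", "is_partner")]))
  }
  area_idx <- match(gt$area, vapply(recs, `[[`, "", "area"))
  gt$channel <- NA_integer_
  gt$amplitude <- NA_real_
  keep <- rep(TRUE, nrow(gt))
  set.seed(seed + 1L)
  for (e in seq_len(nrow(gt))) {
    r <- recs[[area_idx[e]]]
    ch <- sample(2:(nrow(r$data) - 1), 1)
    amp <- cfg$ripple_amp_snr * band_rms[area_idx[e]]
    phase <- stats::runif(1, 0, 2 * pi)
    dur <- gt$duration_ms[e] / 1000
    half <- dur * 1.6                      # support of the envelope
    i0 <- max(1L, round((gt$t_center[e] - half - r$t0) * r$fs))
    i1 <- min(ncol(r$data), round((gt$t_center[e] + half - r$t0) * r$fs))
    if (i1 <= i0) { keep[e] <- FALSE; next }
    rel <- gt$t_center[e] - (r$t0 + (i0 - 1) / r$fs)
    burst <- .gauss_burst(i1 - i0 + 1, r$fs, rel, gt$freq_hz[e], dur, amp,
                          phase)
    recs[[area_idx[e]]]$data[ch, i0:i1] <-
      recs[[area_idx[e]]]$data[ch, i0:i1] + burst
    gt$channel[e] <- r$contact_ids[ch]
    gt$amplitude[e] <- amp
  }
  gt <- gt[keep, , drop = FALSE]
  rownames(gt) <- NULL
  list(recs = recs,
       ground_truth = gt[, c("area", "channel", "t_center", "freq_hz",
                             "duration_ms", "amplitude", "epoch",
                             "trial_id", "is_partner")])
}

#' Inject a stimulus-evoked response with an input-layer sink
#'
#' Adds, at every stimulus onset, (i) a slow negative evoked potential whose
#' amplitude is Gaussian in depth around the input layer -- producing a CSD
#' sink there -- and (ii) a brief high-frequency (400 Hz) burst per contact
#' whose onset latency grows with distance from the input layer, driving the
#' multiunit response-latency estimate.
#'
#' @param rec a [laminar_recording()].
#' @param cfg a [synthetic_config()].
#' @param trials a `trial_table`.
#' @return the recording with the evoked components added, plus attributes
#'   `true_input_contacts` and `true_latency_ms`.
#' @export
inject_evoked_response <- function(rec, cfg, trials) {
  n_ch <- nrow(rec$data)
  depth_gain <- exp(-((seq_len(n_ch) - cfg$input_center)^2) /
                      (2 * cfg$input_sigma^2))
  lat_ms <- cfg$latency_input_ms +
    cfg$latency_slope_ms * abs(seq_len(n_ch) - cfg$input_center)
  dur_lfp <- 0.12
  n_lfp <- round(dur_lfp * rec$fs)
  tt <- (seq_len(n_lfp) - 1) / rec$fs
  lfp_wave <- -sin(pi * tt / dur_lfp)^2          # smooth negative deflection
  n_hf <- round(0.03 * rec$fs)
  tt_hf <- (seq_len(n_hf) - 1) / rec$fs
  hf_wave <- sin(2 * pi * 400 * tt_hf) * exp(-tt_hf / 0.01)
  for (t_s in trials$t_stim_on[!is.na(trials$t_stim_on)]) {
    # slow sink wave: depth-synchronous (onset at the input-layer latency)
    on0 <- round((t_s + cfg$latency_input_ms / 1000 - rec$t0) * rec$fs) + 1
    for (ch in seq_len(n_ch)) {
      if (on0 >= 1 && on0 + n_lfp - 1 <= ncol(rec$data))
        rec$data[ch, on0:(on0 + n_lfp - 1)] <-
          rec$data[ch, on0:(on0 + n_lfp - 1)] +
          cfg$evoked_amp * depth_gain[ch] * lfp_wave
      # multiunit-like burst: onset carries the laminar latency gradient
      on <- round((t_s + lat_ms[ch] / 1000 - rec$t0) * rec$fs) + 1
      if (on < 1 || on + n_hf - 1 > ncol(rec$data)) next
      rec$data[ch, on:(on + n_hf - 1)] <-
        rec$data[ch, on:(on + n_hf - 1)] +
        (0.5 + depth_gain[ch]) * cfg$mua_amp * hf_wave
    }
  }
  # the CSD sink of a Gaussian-in-depth potential is its (negative) second
  # difference; truth = contiguous contacts with sink >= 50% of the maximum
  g <- c(0, depth_gain, 0)
  sink <- -(g[seq_len(n_ch)] - 2 * g[seq_len(n_ch) + 1] + g[seq_len(n_ch) + 2])
  sink[sink < 0] <- 0
  attr(rec, "true_input_contacts") <- which(sink >= 0.5 * max(sink))
  attr(rec, "true_latency_ms") <- lat_ms
  rec
}

#' Reaction times and spike trains for a simulated session
#'
#' Fills in reaction times (`rt`, `t_release`) from the linear RT model --
#' base + condition effects + ripple-occurrence effect + session intercept +
#' Gaussian trial noise -- where a ripple trial is one with a ground-truth
#' event in the sustained epoch, and generates one spike train per contact
#' and area as an inhomogeneous Poisson process: constant baseline plus a
#' Gaussian rate bump at each ground-truth event on that contact.
#'
#' @param cfg a [synthetic_config()].
#' @param ground_truth ground-truth event table from [inject_ripples()].
#' @param seed RNG seed.
#' @param trials trial skeleton from [generate_trial_skeleton()]; when
#'   `NULL` it is regenerated deterministically from `cfg` and `seed`.
#' @param n_trials used only when `trials` is `NULL`.
#' @param duration_s spike-train length; default: covers the last trial.
#' @return list: `trials` (with `rt`, `t_release`, `has_ripple` filled),
#'   `spikes` (named list of `spike_train`s per area and contact),
#'   `session_intercept_ms`.
#' @export
generate_trials_spikes_rts <- function(cfg, ground_truth, seed,
                                       trials = NULL, n_trials = 100,
                                       duration_s = NULL) {
  if (is.null(trials))
    trials <- generate_trial_skeleton(cfg, n_trials, seed)
  set.seed(seed + 1L)
  sus <- canonical_epochs()$sustained
  win <- epoch_windows(trials, sus)
  gt_sus <- ground_truth[ground_truth$epoch == "sustained", , drop = FALSE]
  has_ripple <- vapply(trials$trial_id, function(id) {
    w <- win[win$trial_id == id, , drop = FALSE]
    nrow(w) > 0 && any(gt_sus$t_center >= w$t_start &
                       gt_sus$t_center <= w$t_end)
  }, logical(1))
  trials$has_ripple <- has_ripple
  intercept <- stats::rnorm(1, 0, cfg$rt_session_sd_ms)
  rt <- cfg$rt_base_ms +
    cfg$rt_att_ms * (trials$cue_location == "RF") +
    cfg$rt_size_ms * (trials$stim_size == "small") +
    cfg$rt_focus_ms * (trials$focus == "wide") +
    cfg$rt_ripple_ms * has_ripple +
    intercept + stats::rnorm(nrow(trials), 0, cfg$rt_noise_sd_ms)
  usable <- trials$outcome == "hit" & !is.na(trials$t_dim)
  trials$rt[usable] <- rt[usable]
  trials$t_release[usable] <- trials$t_dim[usable] + rt[usable] / 1000
  trials$rt_valid <- usable & trials$rt >= 0
  if (is.null(duration_s))
    duration_s <- max(trials$t_stim_on, na.rm = TRUE) + 3
  spikes <- list()
  sigma_s <- cfg$spike_sigma_ms / 1000
  areas <- unique(as.character(ground_truth$area))
  if (!length(areas)) areas <- "V1"
  for (area in areas) {
    gt_a <- ground_truth[ground_truth$area == area, , drop = FALSE]
    for (ch in seq_len(cfg$n_channels)) {
      r_max <- cfg$spike_baseline_hz + cfg$spike_ripple_gain_hz
      n_cand <- stats::rpois(1, r_max * duration_s)
      t_cand <- sort(stats::runif(n_cand, 0, duration_s))
      centers <- gt_a$t_center[gt_a$channel == ch]
      lambda <- rep(cfg$spike_baseline_hz, length(t_cand))
      for (t_c in centers)
        lambda <- lambda + cfg$spike_ripple_gain_hz *
          exp(-(t_cand - t_c)^2 / (2 * sigma_s^2))
      keep <- stats::runif(n_cand) < lambda / r_max
      uid <- sprintf("%s_c%02d", area, ch)
      spikes[[uid]] <- spike_train(uid, ch, t_cand[keep])
    }
  }
  list(trials = trials, spikes = spikes, session_intercept_ms = intercept)
}

#' Simulate a complete two-area session
#'
#' Orchestrates the generator: trial skeleton, 1/f background for V1 and V4,
#' evoked laminar response, ripple injection with cross-area partners,
#' reaction times and spike trains. Fully deterministic given `seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param n_trials trials in the session.
#' @param seed RNG seed.
#' @param session_id session label.
#' @param evoked also inject the laminar evoked response (default TRUE).
#' @return list: `trials`, `recordings` (list `V1`, `V4`), `ground_truth`,
#'   `spikes`, `cfg`.
#' @export
simulate_session <- function(cfg = synthetic_config(), n_trials = 60,
                             seed = 1, session_id = "synthetic",
                             evoked = TRUE) {
  trials <- generate_trial_skeleton(cfg, n_trials, seed,
                                    session_id = session_id)
  dur <- max(trials$t_stim_on, na.rm = TRUE) + 3
  v1 <- generate_background(cfg, dur, seed + 10L, area = "V1",
                            session_id = session_id)
  v4 <- generate_background(cfg, dur, seed + 20L, area = "V4",
                            session_id = session_id)
  if (evoked) {
    v1 <- inject_evoked_response(v1, cfg, trials)
    v4 <- inject_evoked_response(v4, cfg, trials)
  }
  inj <- inject_ripples(list(v1, v4), cfg, trials, seed + 30L)
  beh <- generate_trials_spikes_rts(cfg, inj$ground_truth, seed + 40L,
                                    trials = trials, duration_s = dur)
  list(trials = beh$trials, recordings = list(V1 = inj$recs[[1]],
                                              V4 = inj$recs[[2]]),
       ground_truth = inj$ground_truth, spikes = beh$spikes, cfg = cfg)
}

#' Simulate a session-level rate table directly
#'
#' Generates `ripple_rate_table`-shaped data without any LFP: one value per
#' session x condition cell for one epoch, drawn as cell mean + session
#' intercept + noise. Used for calibrating the repeated-measures tests
#' (null tables have all effects zero).
#'
#' @param n_sessions sessions.
#' @param base mean rate, events/s.
#' @param size_effect,att_effect,focus_effect half-differences: the cell
#'   mean is `base + size_effect * s + att_effect * a + focus_effect * f`
#'   with `s`, `a`, `f` in `{-1, +1}` (small/RF/wide = +1).
#' @param session_sd SD of the session random intercept.
#' @param noise_sd SD of the cell noise.
#' @param epoch epoch label.
#' @param seed RNG seed.
#' @return a `ripple_rate_table`.
#' @export
simulate_rate_table <- function(n_sessions = 40, base = 0.065,
                                size_effect = 0.025, att_effect = 0.025,
                                focus_effect = 0.005, session_sd = 0.02,
                                noise_sd = 0.02, epoch = "sustained",
                                seed = 1) {
  set.seed(seed)
  grid <- expand.grid(cue_location = c("away", "RF"),
                      focus = c("narrow", "wide"),
                      stim_size = c("large", "small"),
                      stringsAsFactors = FALSE)
  out <- NULL
  for (s in seq_len(n_sessions)) {
    u <- stats::rnorm(1, 0, session_sd)
    mu <- base + size_effect * ifelse(grid$stim_size == "small", 1, -1) +
      att_effect * ifelse(grid$cue_location == "RF", 1, -1) +
      focus_effect * ifelse(grid$focus == "wide", 1, -1)
    out <- rbind(out, data.frame(
      session = sprintf("s%02d", s), epoch = epoch,
      cue_location = grid$cue_location, focus = grid$focus,
      stim_size = grid$stim_size, n_trials = NA_integer_,
      n_events = NA_integer_,
      rate = pmax(0, mu + u + stats::rnorm(8, 0, noise_sd))))
  }
  class(out) <- c("ripple_rate_table", "data.frame")
  out
}

#' Simulate trial-level reaction times across sessions
#'
#' Direct generator for the mixed-model analyses: trials with balanced
#' condition factors, Bernoulli ripple occurrence, and
#' `rt = base + effects + session intercept + noise`.
#'
#' @param n_sessions,trials_per_session design size.
#' @param base_ms baseline RT.
#' @param ripple_ms,att_ms,size_ms,focus_ms additive effects (ripple / cue
#'   RF / small stimulus / wide focus vs their references).
#' @param p_ripple ripple-trial probability.
#' @param session_sd_ms,noise_sd_ms intercept and trial noise SDs.
#' @param seed RNG seed.
#' @return data.frame with `session`, `cue_location`, `focus`, `stim_size`,
#'   `ripple`, `rt_ms`.
#' @export
simulate_rt_trials <- function(n_sessions = 10, trials_per_session = 200,
                               base_ms = 311, ripple_ms = -3, att_ms = -2,
                               size_ms = -2, focus_ms = 0, p_ripple = 0.3,
                               session_sd_ms = 10, noise_sd_ms = 30,
                               seed = 1) {
  set.seed(seed)
  out <- NULL
  for (s in seq_len(n_sessions)) {
    n <- trials_per_session
    d <- data.frame(
      session = sprintf("s%02d", s),
      cue_location = sample(c("away", "RF"), n, TRUE),
      focus = sample(c("narrow", "wide"), n, TRUE),
      stim_size = sample(c("large", "small"), n, TRUE),
      ripple = ifelse(stats::runif(n) < p_ripple, "yes", "no"))
    u <- stats::rnorm(1, 0, session_sd_ms)
    d$rt_ms <- base_ms + att_ms * (d$cue_location == "RF") +
      size_ms * (d$stim_size == "small") + focus_ms * (d$focus == "wide") +
      ripple_ms * (d$ripple == "yes") + u +
      stats::rnorm(n, 0, noise_sd_ms)
    out <- rbind(out, d)
  }
  out
}
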