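#' Ripple detector configuration
#'
#' Defaults implement the dual-threshold band-power detector: the
#' rereferenced LFP is band-passed 80-250 Hz with a zero-phase FIR, squared,
#' and z-scored per channel over the entire recording. Runs above 3.5 SD are
#' candidate events; gaps under 5 ms are merged; events outside 30-100 ms are
#' dropped; candidates whose maximum does not exceed 5 SD are dropped; and a
#' spectral check rejects events whose peak frequency (Hanning spectrum of a
#' 200-ms window of the raw rereferenced LFP, baseline-normalized) falls
#' below 80 or above 200 Hz.
#'
#' @param band ripple band-pass, Hz.
#' @param z_candidate candidate threshold, SD units.
#' @param z_confirm confirmation threshold applied to the event maximum, SD.
#' @param merge_gap_ms inter-event gaps shorter than this are merged, ms.
#' @param dur_min_ms,dur_max_ms accepted event duration range, ms.
#' @param pf_min_hz,pf_max_hz accepted peak-frequency range, Hz (events with
#'   peak frequency below/above are rejected as false detections).
#' @param pf_window_ms spectral-validation window length, ms.
#' @param pf_search_hz frequency range searched for the spectral peak, Hz
#'   (wide enough that low-frequency transients are seen and rejected).
#' @param smooth_ms optional boxcar smoothing of the squared trace before
#'   z-scoring, ms; 0 (default) disables it.
#' @param transition_hz FIR transition width for the ripple band-pass.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(band = c(80, 250), z_candidate = 3.5,
                             z_confirm = 5, merge_gap_ms = 5,
                             dur_min_ms = 30, dur_max_ms = 100,
                             pf_min_hz = 80, pf_max_hz = 200,
                             pf_window_ms = 200,
                             pf_search_hz = c(30, 300),
                             smooth_ms = 0, transition_hz = 10) {
  if (z_confirm < z_candidate)
    stop("`z_confirm` must be at least `z_candidate`")
  if (dur_min_ms >= dur_max_ms) stop("`dur_min_ms` must be below `dur_max_ms`")
  if (pf_min_hz >= pf_max_hz) stop("`pf_min_hz` must be below `pf_max_hz`")
  structure(list(band = band, z_candidate = z_candidate,
                 z_confirm = z_confirm, merge_gap_ms = merge_gap_ms,
                 dur_min_ms = dur_min_ms, dur_max_ms = dur_max_ms,
                 pf_min_hz = pf_min_hz, pf_max_hz = pf_max_hz,
                 pf_window_ms = pf_window_ms, pf_search_hz = pf_search_hz,
                 smooth_ms = smooth_ms, transition_hz = transition_hz),
            class = "detection_config")
}

#' Normalized ripple-band power trace
#'
#' Band-passes each channel in the ripple band (zero-phase FIR), squares the
#' result and z-scores it using the mean and SD of that channel computed over
#' the entire recording, so the trace is in SD units and the detector is
#' invariant to overall signal scaling.
#'
#' @param rec a rereferenced [laminar_recording()].
#' @param cfg a [detection_config()].
#' @return numeric matrix, channels x samples, z units.
#' @export
ripple_envelope <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (rec$fs < 2 * cfg$band[2])
    stop("sampling rate too low for the requested ripple band")
  t(apply(rec$data, 1, function(ch) {
    bp <- fir_bandpass_zerophase(ch, rec$fs, cfg$band,
                                 transition_hz = cfg$transition_hz)
    p <- bp^2
    if (cfg$smooth_ms > 0) {
      k <- max(1L, round(cfg$smooth_ms * rec$fs / 1000))
      p <- as.numeric(stats::filter(p, rep(1 / k, k), sides = 2))
      p[is.na(p)] <- 0
    }
    s <- stats::sd(p)
    if (!is.finite(s) || s == 0)
      stop("degenerate channel: ripple-band power has zero variance")
    (p - mean(p)) / s
  }))
}

#' Candidate events from a normalized power trace
#'
#' Maximal runs above the candidate threshold; runs separated by gaps shorter
#' than `merge_gap_ms` are merged; merged runs are gated to the accepted
#' duration range; finally runs whose maximum does not exceed the
#' confirmation threshold are discarded.
#'
#' @param env numeric vector, z units (one channel).
#' @param fs sampling rate, Hz.
#' @param cfg a [detection_config()].
#' @param t0 session time of `env[1]`, seconds.
#' @return data.frame with `i_start`, `i_end` (sample indices), `t_start`,
#'   `t_end`, `t_center`, `duration_ms`, `peak_z`.
#' @export
detect_candidates <- function(env, fs, cfg = detection_config(), t0 = 0) {
  if (!all(is.finite(env))) stop("`env` must be finite")
  empty <- data.frame(i_start = integer(), i_end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      t_center = numeric(), duration_ms = numeric(),
                      peak_z = numeric())
  r <- rle(env > cfg$z_candidate)
  if (!any(r$values)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i_start <- starts[r$values]
  i_end <- ends[r$values]
  # merge runs separated by < merge_gap_ms
  if (length(i_start) > 1) {
    gap_ms <- (i_start[-1] - i_end[-length(i_end)] - 1L) / fs * 1000
    grp <- cumsum(c(0L, as.integer(!(gap_ms < cfg$merge_gap_ms))))
    i_start <- tapply(i_start, grp, min)
    i_end <- tapply(i_end, grp, max)
  }
  dur_ms <- (i_end - i_start + 1L) / fs * 1000
  keep <- dur_ms >= cfg$dur_min_ms & dur_ms <= cfg$dur_max_ms
  i_start <- i_start[keep]; i_end <- i_end[keep]; dur_ms <- dur_ms[keep]
  if (!length(i_start)) return(empty)
  peak_z <- mapply(function(a, b) max(env[a:b]), i_start, i_end)
  keep <- peak_z > cfg$z_confirm
  out <- data.frame(
    i_start = as.integer(i_start[keep]), i_end = as.integer(i_end[keep]),
    duration_ms = dur_ms[keep], peak_z = peak_z[keep]
  )
  out$t_start <- t0 + (out$i_start - 1) / fs
  out$t_end <- t0 + (out$i_end - 1) / fs
  out$t_center <- (out$t_start + out$t_end) / 2
  rownames(out) <- NULL
  out[, c("i_start", "i_end", "t_start", "t_end", "t_center",
          "duration_ms", "peak_z")]
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# one-sided Hanning-tapered power spectrum of a window (mean-subtracted)
.window_spectrum <- function(x, fs) {
  n <- length(x)
  w <- .hann(n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nf <- floor(n / 2) + 1
  p <- Mod(X[seq_len(nf)])^2 / (n * sum(w^2))
  # double the bins with a conjugate partner (all interior bins; for odd n
  # the last bin is paired too)
  dbl <- if (n %% 2 == 0) seq(2, nf - 1) else seq(2, nf)
  p[dbl] <- 2 * p[dbl]
  list(freq = (seq_len(nf) - 1) * fs / n, power = p)
}

# average spectrum over non-overlapping windows: the channel's 1/f baseline
.baseline_spectrum <- function(x, fs, win_n) {
  nwin <- floor(length(x) / win_n)
  if (nwin < 1) stop("signal shorter than the spectral window")
  acc <- NULL
  for (k in seq_len(nwin)) {
    sp <- .window_spectrum(x[((k - 1) * win_n + 1):(k * win_n)], fs)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  list(freq = sp$freq, power = acc / nwin)
}

#' Spectral validation of a candidate event
#'
#' Computes the Hanning-tapered power spectrum of the raw rereferenced LFP in
#' a window centred on the event, divides it by the channel's average
#' (baseline) spectrum to flatten the 1/f background, and takes the peak
#' frequency as the argmax of that ratio inside `pf_search_hz`. The event is
#' kept iff the peak frequency lies within `[pf_min_hz, pf_max_hz]`.
#'
#' @param t_center event centre, seconds (session clock).
#' @param sig raw rereferenced signal of the event's channel.
#' @param fs sampling rate, Hz.
#' @param cfg a [detection_config()].
#' @param t0 session time of `sig[1]`.
#' @param baseline optional precomputed baseline spectrum (as returned by the
#'   internal averager); computed from `sig` when `NULL`.
#' @return list with `keep` (logical) and `peak_freq_hz`.
#' @export
validate_peak_frequency <- function(t_center, sig, fs,
                                    cfg = detection_config(), t0 = 0,
                                    baseline = NULL) {
  win_n <- round(cfg$pf_window_ms / 1000 * fs)
  ic <- round((t_center - t0) * fs) + 1
  half <- floor(win_n / 2)
  a <- ic - half; b <- ic + half
  if (a < 1 || b > length(sig)) {      # shrink symmetrically at the borders
    half <- min(ic - 1, length(sig) - ic)
    a <- ic - half; b <- ic + half
  }
  if (b - a + 1 < 8) return(list(keep = FALSE, peak_freq_hz = NA_real_))
  sp <- .window_spectrum(sig[a:b], fs)
  base <- if (is.null(baseline)) .baseline_spectrum(sig, fs, win_n)
          else baseline
  rel <- sp$power / (stats::approx(base$freq, base$power, xout = sp$freq,
                                   rule = 2)$y + 1e-12)
  inb <- sp$freq >= cfg$pf_search_hz[1] & sp$freq <= cfg$pf_search_hz[2]
  pf <- sp$freq[inb][which.max(rel[inb])]
  list(keep = pf >= cfg$pf_min_hz && pf <= cfg$pf_max_hz, peak_freq_hz = pf)
}

#' Detect ripple events on every channel of a rereferenced recording
#'
#' Composition of [ripple_envelope()], [detect_candidates()] and
#' [validate_peak_frequency()], run per channel. Events are reported in
#' session time, tagged with session, area and (parent) contact id.
#'
#' @param rec a rereferenced [laminar_recording()].
#' @param cfg a [detection_config()].
#' @return data.frame with columns `session`, `area`, `channel`, `t_start`,
#'   `t_end`, `t_center`, `duration_ms`, `peak_z`, `peak_freq_hz`.
#' @export
detect_ripples <- function(rec, cfg = detection_config()) {
  env <- ripple_envelope(rec, cfg)
  win_n <- round(cfg$pf_window_ms / 1000 * rec$fs)
  out <- vector("list", nrow(env))
  for (ch in seq_len(nrow(env))) {
    cand <- detect_candidates(env[ch, ], rec$fs, cfg, t0 = rec$t0)
    if (!nrow(cand)) next
    base <- .baseline_spectrum(rec$data[ch, ], rec$fs, win_n)
    val <- lapply(cand$t_center, validate_peak_frequency,
                  sig = rec$data[ch, ], fs = rec$fs, cfg = cfg,
                  t0 = rec$t0, baseline = base)
    keep <- vapply(val, `[[`, logical(1), "keep")
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    cand$peak_freq_hz <- vapply(val, `[[`, numeric(1), "peak_freq_hz")[keep]
    cand$session <- rec$session_id
    cand$area <- rec$area
    cand$channel <- rec$contact_ids[ch]
    out[[ch]] <- cand
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(session = character(), area = character(),
                      channel = integer(), t_start = numeric(),
                      t_end = numeric(), t_center = numeric(),
                      duration_ms = numeric(), peak_z = numeric(),
                      peak_freq_hz = numeric())
  rownames(out) <- NULL
  out[, c("session", "area", "channel", "t_start", "t_end", "t_center",
          "duration_ms", "peak_z", "peak_freq_hz")]
}

#' Label events with trial and epoch
#'
#' Assigns each event the epoch whose window contains its centre (and the
#' corresponding trial id). Events outside every epoch window get `NA`.
#'
#' @param events event data.frame from [detect_ripples()].
#' @param trials a `trial_table`.
#' @param epochs named list of [epoch_definition()]s
#'   (default [canonical_epochs()]).
#' @return `events` with `epoch` and `trial_id` columns added.
#' @export
assign_epochs <- function(events, trials, epochs = canonical_epochs()) {
  events$epoch <- NA_character_
  events$trial_id <- NA
  for (ep in epochs) {
    win <- epoch_windows(trials, ep)
    if (!nrow(win)) next
    for (k in seq_len(nrow(win))) {
      hit <- events$t_center >= win$t_start[k] &
             events$t_center <= win$t_end[k]
      events$epoch[hit] <- ep$name
      events$trial_id[hit] <- win$trial_id[k]
    }
  }
  events
}

#' Merge detections across channels into area-level events
#'
#' A burst on one parent contact appears on both flanking derived channels
#' after bipolar rereferencing, and genuine ripples can span neighbouring
#' contacts; analyses phrased as "a ripple on any contact" (cooccurrence,
#' reaction times, area-level rates) therefore need events deduplicated in
#' time. Detections within `merge_ms` of a growing cluster (per session and
#' area) are collapsed into one event at the member mean centre time.
#'
#' @param events event data.frame from [detect_ripples()].
#' @param merge_ms cluster gap, ms.
#' @return data.frame with one row per area-level event (`session`, `area`,
#'   `t_center`, `n_channels`, and the mean `duration_ms` / max `peak_z` of
#'   the members).
#' @export
area_events <- function(events, merge_ms = 10) {
  if (!nrow(events))
    return(data.frame(session = character(), area = character(),
                      t_center = numeric(), n_channels = integer(),
                      duration_ms = numeric(), peak_z = numeric()))
  out <- lapply(split(events, list(events$session, events$area),
                      drop = TRUE), function(ev) {
    ev <- ev[order(ev$t_center), , drop = FALSE]
    grp <- cumsum(c(0, diff(ev$t_center) * 1000 > merge_ms))
    data.frame(
      session = ev$session[1], area = ev$area[1],
      t_center = as.numeric(tapply(ev$t_center, grp, mean)),
      n_channels = as.integer(tapply(ev$channel, grp,
                                     function(z) length(unique(z)))),
      duration_ms = as.numeric(tapply(ev$duration_ms, grp, mean)),
      peak_z = as.numeric(tapply(ev$peak_z, grp, max))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-epoch summaries of event duration and peak frequency
#'
#' Mean and SEM of duration and peak frequency per epoch, plus Kruskal-Wallis
#' tests across epochs for both quantities. Epochs with no events are simply
#' absent; with fewer than two epochs the tests are skipped (`NULL`).
#'
#' @param events event data.frame carrying an `epoch` column
#'   (see [assign_epochs()]).
#' @return list with `summary` (data.frame), `kw_duration`, `kw_peak_freq`
#'   (each `NULL` or a list with `statistic`, `df`, `p.value`).
#' @export
summarize_events <- function(events) {
  ev <- events[!is.na(events$epoch), , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  sm <- do.call(rbind, lapply(split(ev, ev$epoch), function(d) data.frame(
    epoch = d$epoch[1], n = nrow(d),
    duration_mean_ms = mean(d$duration_ms), duration_sem_ms = sem(d$duration_ms),
    peak_freq_mean_hz = mean(d$peak_freq_hz), peak_freq_sem_hz = sem(d$peak_freq_hz)
  )))
  rownames(sm) <- NULL
  kw <- function(value) {
    if (length(unique(ev$epoch)) < 2) return(NULL)
    if (length(unique(value)) < 2)            # no variation at all: no effect
      return(list(statistic = 0, df = length(unique(ev$epoch)) - 1,
                  p.value = 1))
    k <- stats::kruskal.test(value, factor(ev$epoch))
    list(statistic = unname(k$statistic), df = unname(k$parameter),
         p.value = k$p.value)
  }
  list(summary = sm, kw_duration = kw(ev$duration_ms),
       kw_peak_freq = kw(ev$peak_freq_hz))
}
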