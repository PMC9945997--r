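#' Current source density from a trial-averaged laminar LFP
#'
#' Standard second-spatial-difference estimator on equally spaced contacts:
#' `csd_i(t) = -(x_{i-1}(t) - 2 x_i(t) + x_{i+1}(t)) / h^2`, with tissue
#' conductivity absorbed into the (arbitrary) units. Sinks are negative. The
#' two edge contacts have no estimate; with `vaknin = TRUE` the edge
#' potentials are replicated outward so every contact gets an estimate.
#'
#' @param rec a [laminar_recording()] holding the trial-averaged LFP.
#' @param vaknin replicate boundary potentials to keep edge contacts.
#' @return list of class `csd_profile`: `depths` (um, per estimated contact),
#'   `contact_ids`, `times` (s), `csd` (n_depth x n_time).
#' @export
compute_csd <- function(rec, vaknin = FALSE) {
  stopifnot(inherits(rec, "laminar_recording"))
  x <- rec$data
  if (nrow(x) < 3) stop("CSD needs at least 3 contacts")
  h <- rec$contact_spacing
  if (vaknin) {
    x <- rbind(x[1, ], x, x[nrow(x), ])
    ids <- rec$contact_ids
  } else {
    ids <- rec$contact_ids[2:(nrow(x) - 1)]
  }
  i <- 2:(nrow(x) - 1)
  csd <- -(x[i - 1, , drop = FALSE] - 2 * x[i, , drop = FALSE] +
             x[i + 1, , drop = FALSE]) / h^2
  structure(list(depths = (match(ids, rec$contact_ids) - 1) * h,
                 contact_ids = ids, times = sample_times(rec), csd = csd),
            class = "csd_profile")
}

#' Trial-average a recording around an anchor
#'
#' Utility for CSD and latency analyses: aligns every trial at the anchor
#' timestamp and averages, returning a `laminar_recording` whose time axis is
#' relative to the anchor (`t0 = -pre_s`).
#'
#' @param rec a [laminar_recording()].
#' @param trials a `trial_table`.
#' @param anchor column name of the anchor timestamp (default `"t_stim_on"`).
#' @param pre_s,post_s window around the anchor, seconds.
#' @return a `laminar_recording` of the trial-averaged window.
#' @export
trial_average <- function(rec, trials, anchor = "t_stim_on",
                          pre_s = 0.1, post_s = 0.25) {
  at <- trials[[anchor]]
  at <- at[!is.na(at)]
  n_pre <- round(pre_s * rec$fs); n_post <- round(post_s * rec$fs)
  acc <- matrix(0, nrow(rec$data), n_pre + n_post + 1)
  used <- 0
  for (t_a in at) {
    ic <- round((t_a - rec$t0) * rec$fs) + 1
    a <- ic - n_pre; b <- ic + n_post
    if (a < 1 || b > ncol(rec$data)) next
    acc <- acc + rec$data[, a:b, drop = FALSE]
    used <- used + 1
  }
  if (used == 0) stop("no trial window fits inside the recording")
  laminar_recording(acc / used, fs = rec$fs, area = rec$area,
                    session_id = rec$session_id,
                    contact_spacing = rec$contact_spacing,
                    contact_ids = rec$contact_ids, t0 = -n_pre / rec$fs)
}

#' Multiunit response latency per contact
#'
#' High-passes each contact, rectifies, aligns trials at stimulus onset and
#' averages; latency is the first post-stimulus time at which the average
#' exceeds the pre-stimulus baseline mean + `thresh_sd` SD continuously for
#' at least `persist_ms`. Contacts with no such crossing within
#' `max_latency_ms` get `NA`. The persistence window defaults to twice the
#' envelope smoothing width: smoothed noise is autocorrelated over
#' `smooth_ms`, so a shorter persistence would no longer discriminate
#' against noise runs.
#'
#' @param rec a [laminar_recording()] (broadband enough to carry multiunit
#'   energy above `highpass_hz`).
#' @param trials a `trial_table` with at least 20 stimulus-aligned trials.
#' @param anchor anchor timestamp column (default `"t_stim_on"`).
#' @param highpass_hz lower edge of the multiunit band, Hz.
#' @param baseline_ms pre-stimulus baseline length, ms.
#' @param max_latency_ms search horizon after the anchor, ms.
#' @param thresh_sd threshold in baseline SD units.
#' @param persist_ms minimum supra-threshold run, ms.
#' @param smooth_ms boxcar applied to the rectified trace (the standard
#'   multiunit-envelope smoothing; without it the rectified oscillation dips
#'   below threshold every half cycle), ms.
#' @return data.frame with `contact_id` and `latency_ms`.
#' @export
response_latency <- function(rec, trials, anchor = "t_stim_on",
                             highpass_hz = 300, baseline_ms = 250,
                             max_latency_ms = 200, thresh_sd = 3,
                             persist_ms = 10, smooth_ms = 5) {
  if (sum(!is.na(trials[[anchor]])) < 20)
    stop("response latency needs at least 20 stimulus-aligned trials")
  band <- c(highpass_hz, min(0.45 * rec$fs, rec$fs / 2 - 1))
  k <- max(1L, round(smooth_ms / 1000 * rec$fs))
  hp <- rec
  hp$data <- t(apply(rec$data, 1, function(ch) {
    y <- abs(fir_bandpass_zerophase(ch, rec$fs, band, transition_hz = 50))
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    y[is.na(y)] <- 0
    y
  }))
  avg <- trial_average(hp, trials, anchor, pre_s = baseline_ms / 1000,
                       post_s = max_latency_ms / 1000)
  tt <- sample_times(avg)
  persist_n <- max(1L, round(persist_ms / 1000 * rec$fs))
  lat <- rep(NA_real_, nrow(avg$data))
  for (ch in seq_len(nrow(avg$data))) {
    y <- avg$data[ch, ]
    basel <- y[tt < 0]
    thr <- mean(basel) + thresh_sd * stats::sd(basel)
    post <- which(tt >= 0)
    above <- y[post] > thr
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= persist_n)
    if (length(hit))
      lat[ch] <- tt[post[starts[hit[1]]]] * 1000
  }
  data.frame(contact_id = avg$contact_ids, latency_ms = lat)
}

#' Assign contacts to laminar compartments
#'
#' The input layer is the contiguous block of contacts whose CSD sink (at the
#' time of the strongest early sink) reaches at least `sink_frac` of the
#' maximal sink amplitude; the block must contain the minimum-latency
#' contact. Contacts above the block are superficial, below it deep; contacts
#' without a CSD estimate are excluded. If the strongest-sink contact and the
#' fastest-latency contact disagree by more than `max_disagreement` contacts
#' the assignment is ambiguous and an explicit override is required.
#'
#' @param csd a `csd_profile` from [compute_csd()].
#' @param latencies data.frame from [response_latency()].
#' @param all_contact_ids full ordered contact list of the probe (default:
#'   the latency table's contacts).
#' @param sink_frac fraction of the maximal sink amplitude that defines the
#'   input block.
#' @param sink_window_ms the sink profile is averaged over this window around
#'   the strongest-sink time (noise suppression), ms.
#' @param search_window_s time window (relative to the alignment anchor) in
#'   which the early sink is sought; the pre-anchor period serves as a
#'   per-contact baseline that is subtracted first.
#' @param max_disagreement tolerated sink/latency offset, contacts.
#' @param override optional data.frame (`contact_id`, `label`) that is
#'   returned as-is (manual assignment).
#' @return list of class `layer_assignment`: `labels` (data.frame
#'   `contact_id`, `label`), `n_contacts` (named count per label).
#' @export
assign_layers <- function(csd, latencies, all_contact_ids = NULL,
                          sink_frac = 0.5, sink_window_ms = 10,
                          search_window_s = c(0, 0.15),
                          max_disagreement = 2, override = NULL) {
  if (!is.null(override)) {
    stopifnot(all(c("contact_id", "label") %in% names(override)))
    return(.layer_assignment(override))
  }
  if (is.null(all_contact_ids)) all_contact_ids <- latencies$contact_id
  mat <- csd$csd
  pre <- csd$times < 0
  if (any(pre)) mat <- mat - rowMeans(mat[, pre, drop = FALSE])
  insearch <- which(csd$times >= search_window_s[1] &
                    csd$times <= search_window_s[2])
  if (!length(insearch)) insearch <- seq_along(csd$times)
  if (min(mat[, insearch]) >= 0) stop("no CSD sink found")
  dt <- if (length(csd$times) > 1) csd$times[2] - csd$times[1] else 1
  k <- max(1L, round(sink_window_ms / 1000 / dt))
  mat <- t(apply(mat, 1, function(z) {        # running mean over the window
    y <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
    y[is.na(y)] <- 0
    y
  }))
  t_sink <- insearch[which.min(apply(mat[, insearch, drop = FALSE], 2, min))]
  prof <- mat[, t_sink]
  c_sink <- which.min(prof)
  lat <- latencies$latency_ms[match(csd$contact_ids, latencies$contact_id)]
  if (all(is.na(lat))) stop("no contact has a measurable response latency")
  c_lat <- which.min(lat)
  if (abs(c_sink - c_lat) > max_disagreement)
    stop("ambiguous laminar assignment: strongest sink (contact ",
         csd$contact_ids[c_sink], ") and fastest latency (contact ",
         csd$contact_ids[c_lat],
         ") disagree by more than ", max_disagreement,
         " contacts; supply an override")
  deep_enough <- prof <= sink_frac * prof[c_sink]  # both negative
  block <- c_sink
  while (block[1] > 1 && deep_enough[block[1] - 1])
    block <- c(block[1] - 1, block)
  while (block[length(block)] < length(prof) &&
         deep_enough[block[length(block)] + 1])
    block <- c(block, block[length(block)] + 1)
  block <- sort(unique(c(block, c_lat)))        # must contain fastest contact
  block <- seq(min(block), max(block))
  labels <- data.frame(contact_id = all_contact_ids,
                       label = "excluded", stringsAsFactors = FALSE)
  pos <- match(csd$contact_ids, all_contact_ids)  # estimated contacts only
  rel <- seq_along(pos)
  labels$label[pos[rel < min(block)]] <- "superficial"
  labels$label[pos[rel %in% block]] <- "input"
  labels$label[pos[rel > max(block)]] <- "deep"
  .layer_assignment(labels)
}

.layer_assignment <- function(labels) {
  labels$label <- as.character(labels$label)
  n <- table(factor(labels$label,
                    levels = c("superficial", "input", "deep", "excluded")))
  structure(list(labels = labels, n_contacts = c(n)),
            class = "layer_assignment")
}

#' Read / write a layer assignment as `layers.csv`
#' @param path CSV path (`contact_id`, `label`).
#' @return `load_layers` returns a `layer_assignment`.
#' @export
load_layers <- function(path)
  .layer_assignment(utils::read.csv(path, stringsAsFactors = FALSE))

#' @rdname load_layers
#' @param layers a `layer_assignment`.
#' @export
write_layers <- function(layers, path) {
  utils::write.csv(layers$labels, path, row.names = FALSE)
  invisible(path)
}

#' Contact-count-normalized ripple rate per layer
#'
#' Layer thickness varies, so the per-layer event rate is divided by the
#' number of contacts in the layer:
#' `rate = [n_events / (n_trials * epoch_duration)] / n_contacts`.
#'
#' @param events epoch-labelled event data.frame (see [assign_epochs()]) with
#'   a `channel` column.
#' @param layers a `layer_assignment`.
#' @param trials a `trial_table`.
#' @param epoch an [epoch_definition()]; events are restricted to it.
#' @return data.frame with `layer`, `n_contacts`, `n_events`,
#'   `rate_per_contact` (events/s/contact). Layers with zero contacts are
#'   excluded with a message.
#' @export
layer_ripple_rates <- function(events, layers, trials, epoch) {
  win <- epoch_windows(trials, epoch)
  total_t <- sum(win$t_end - win$t_start)
  if ("epoch" %in% names(events))
    events <- events[!is.na(events$epoch) & events$epoch == epoch$name, ,
                     drop = FALSE]
  lab <- layers$labels$label[match(events$channel, layers$labels$contact_id)]
  if (anyNA(lab)) stop("some events sit on contacts without a layer label")
  out <- NULL
  for (layer in c("superficial", "input", "deep")) {
    n_c <- sum(layers$labels$label == layer)
    if (n_c == 0) { message("layer `", layer, "` has no contacts; excluded")
                    next }
    n_e <- sum(lab == layer)
    out <- rbind(out, data.frame(
      layer = layer, n_contacts = n_c, n_events = n_e,
      rate_per_contact = (n_e / total_t) / n_c))
  }
  rownames(out) <- NULL
  out
}
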