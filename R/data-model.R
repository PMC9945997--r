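#' Laminar recording container
#'
#' A `laminar_recording` holds a channels-by-samples LFP matrix from one
#' laminar probe together with its acquisition metadata. All times in the
#' package are seconds on a single per-session clock; sample `n` of the
#' recording sits at `t0 + (n - 1) / fs`.
#'
#' @param data numeric matrix, channels x samples, microvolts. No NAs.
#' @param fs sampling rate, Hz (> 0).
#' @param area area label, `"V1"` or `"V4"`.
#' @param session_id session identifier string.
#' @param contact_spacing spacing between adjacent contacts, micrometers.
#' @param contact_ids ordered contact identifiers (default `1:nrow(data)`).
#' @param t0 session time of the first sample, seconds.
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(data, fs, area = c("V1", "V4"),
                              session_id = "session",
                              contact_spacing = 150,
                              contact_ids = NULL, t0 = 0) {
  area <- match.arg(area)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (anyNA(data)) stop("`data` contains missing values")
  if (nrow(data) < 3) stop("a laminar recording needs at least 3 channels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (!is.numeric(contact_spacing) || contact_spacing <= 0)
    stop("`contact_spacing` must be positive")
  if (is.null(contact_ids)) contact_ids <- seq_len(nrow(data))
  if (length(contact_ids) != nrow(data))
    stop("`contact_ids` length must equal the channel count")
  structure(list(
    session_id = as.character(session_id), area = area,
    data = data, fs = as.numeric(fs),
    contact_spacing = as.numeric(contact_spacing),
    contact_ids = contact_ids, t0 = as.numeric(t0)
  ), class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf(
    "<laminar_recording> %s/%s: %d channels x %d samples @ %.5g Hz (%.1f s), %g um spacing\n",
    x$session_id, x$area, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs, x$contact_spacing))
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param rec a `laminar_recording`.
#' @return integer count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Sample times of a recording (seconds, session clock)
#' @param rec a `laminar_recording`.
#' @return numeric vector of length `n_samples(rec)`.
#' @export
sample_times <- function(rec) rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$fs

#' Write / read a laminar recording
#'
#' On-disk format: `<stem>.lfp.f32`, raw little-endian 32-bit floats in
#' channel-major order (all samples of channel 1, then channel 2, ...), plus
#' a JSON sidecar `<stem>.json` carrying `fs`, `area`, `session_id`,
#' `contact_spacing_um`, `contact_ids`, `t0` and `n_channels`.
#'
#' @param rec a `laminar_recording`.
#' @param stem path stem; `.lfp.f32` and `.json` are appended.
#' @return `write_recording` returns `stem` invisibly; `load_recording`
#'   returns a validated `laminar_recording`.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "laminar_recording"))
  con <- file(paste0(stem, ".lfp.f32"), "wb")
  on.exit(close(con))
  # channel-major: write each channel's samples contiguously
  writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
  meta <- list(
    session_id = rec$session_id, area = rec$area, fs = rec$fs,
    contact_spacing_um = rec$contact_spacing,
    contact_ids = rec$contact_ids, t0 = rec$t0,
    n_channels = nrow(rec$data), n_samples = ncol(rec$data)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
load_recording <- function(stem) {
  raw_path <- paste0(stem, ".lfp.f32")
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path))
    stop("missing JSON sidecar: ", meta_path)
  if (!file.exists(raw_path))
    stop("missing LFP payload: ", raw_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "area", "n_channels"))
    if (is.null(meta[[f]])) stop("sidecar lacks required field `", f, "`")
  if (meta$fs <= 0) stop("sidecar fs must be positive")
  n_total <- file.size(raw_path) / 4
  nch <- as.integer(meta$n_channels)
  if (n_total %% nch != 0)
    stop("payload size is not a multiple of the channel count")
  vals <- readBin(raw_path, "numeric", n = n_total, size = 4,
                  endian = "little")
  if (!is.null(meta$n_samples) && n_total / nch != meta$n_samples)
    stop("channel count / sample count mismatch between sidecar and payload")
  data <- t(matrix(vals, ncol = nch))
  laminar_recording(
    data, fs = meta$fs, area = meta$area,
    session_id = meta$session_id %||% "session",
    contact_spacing = meta$contact_spacing_um %||% 150,
    contact_ids = meta$contact_ids %||% seq_len(nch),
    t0 = meta$t0 %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.trial_factor_levels <- list(
  cue_location = c("away", "RF"),
  focus = c("narrow", "wide"),
  stim_size = c("large", "small"),
  outcome = c("hit", "miss", "false_alarm", "fixation_break", "blank")
)

#' Load a trial table
#'
#' Reads `trials.csv` (columns: `trial_id`, `cue_location`, `focus`,
#' `stim_size`, `t_fix`, `t_cue_on`, `t_cue_off`, `t_stim_on`, `t_dim`,
#' `t_release`, `outcome`, optionally `rt` and `session_id`) into a typed
#' trial table. Reaction time is recomputed as `(t_release - t_dim) * 1000` ms
#' when both timestamps are present; negative values are kept but flagged in
#' `rt_valid`. Fixation-break trials are retained, flagged in `is_break`.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @return A data.frame of class `trial_table`.
#' @export
load_trials <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "cue_location", "focus", "stim_size", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trials table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (col in names(.trial_factor_levels)) {
    lev <- .trial_factor_levels[[col]]
    bad <- setdiff(unique(stats::na.omit(df[[col]])), lev)
    if (length(bad))
      stop("unknown level(s) in `", col, "`: ", paste(bad, collapse = ", "))
    df[[col]] <- factor(df[[col]], levels = lev)
  }
  for (col in c("t_fix", "t_cue_on", "t_cue_off", "t_stim_on",
                "t_dim", "t_release"))
    if (!col %in% names(df)) df[[col]] <- NA_real_ else
      df[[col]] <- as.numeric(df[[col]])
  both <- !is.na(df$t_release) & !is.na(df$t_dim)
  rt <- rep(NA_real_, nrow(df))
  rt[both] <- (df$t_release[both] - df$t_dim[both]) * 1000
  df$rt <- rt
  df$rt_valid <- !is.na(rt) & rt >= 0
  df$is_break <- df$outcome == "fixation_break"
  ok <- stats::complete.cases(df[, c("t_cue_on", "t_cue_off", "t_stim_on")])
  if (any(ok & !(df$t_cue_on < df$t_cue_off & df$t_cue_off < df$t_stim_on)))
    stop("trial timestamps out of order (cue_on < cue_off < stim_on violated)")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Epoch definitions
#'
#' An epoch is a fixed window relative to a per-trial anchor event. The three
#' canonical task epochs are: precue (200 ms after fixation onset, before the
#' cue), postcue (800 ms starting at cue offset) and sustained (300-750 ms
#' after stimulus onset).
#'
#' @param name epoch name.
#' @param anchor one of `"fixation"`, `"cue_off"`, `"stim_on"`, `"trial_gap"`.
#' @param offset_start,offset_end window bounds relative to the anchor,
#'   seconds; `offset_end > offset_start`.
#' @return A list of class `epoch_definition`.
#' @export
epoch_definition <- function(name, anchor = c("fixation", "cue_off",
                                              "stim_on", "trial_gap"),
                             offset_start, offset_end) {
  anchor <- match.arg(anchor)
  if (!(offset_end > offset_start))
    stop("`offset_end` must exceed `offset_start`")
  structure(list(name = name, anchor = anchor,
                 offset_start = offset_start, offset_end = offset_end),
            class = "epoch_definition")
}

#' @rdname epoch_definition
#' @param postcue_end_anchored if `TRUE`, place the 800-ms postcue window so
#'   it ends at stimulus onset instead of starting at cue offset (the delay is
#'   1000 ms, so the two placements differ by 200 ms).
#' @return `canonical_epochs` returns a named list of the three task epochs.
#' @export
canonical_epochs <- function(postcue_end_anchored = FALSE) {
  postcue <- if (postcue_end_anchored)
    epoch_definition("postcue", "cue_off", 0.2, 1.0)
  else
    epoch_definition("postcue", "cue_off", 0.0, 0.8)
  list(
    precue    = epoch_definition("precue", "fixation", 0.0, 0.2),
    postcue   = postcue,
    sustained = epoch_definition("sustained", "stim_on", 0.3, 0.75)
  )
}

.anchor_column <- c(fixation = "t_fix", cue_off = "t_cue_off",
                    stim_on = "t_stim_on", trial_gap = "t_release")
# the anchor event that follows each anchor within a trial; windows must not
# cross it
.next_anchor_column <- c(t_fix = "t_cue_on", t_cue_off = "t_stim_on",
                         t_stim_on = "t_dim", t_release = NA)

#' Epoch windows in session time
#'
#' Expands an epoch definition over a trial table into absolute
#' `(t_start, t_end)` windows. Trials missing the anchor timestamp are
#' skipped; windows that would extend past the next within-trial anchor are
#' dropped with a warning (they never occur under canonical task timing).
#'
#' @param trials a `trial_table`.
#' @param epoch an `epoch_definition`.
#' @return data.frame with `trial_id`, `t_start`, `t_end`.
#' @export
epoch_windows <- function(trials, epoch) {
  stopifnot(inherits(epoch, "epoch_definition"))
  acol <- .anchor_column[[epoch$anchor]]
  anchor_t <- trials[[acol]]
  keep <- !is.na(anchor_t)
  out <- data.frame(
    trial_id = trials$trial_id[keep],
    t_start = anchor_t[keep] + epoch$offset_start,
    t_end = anchor_t[keep] + epoch$offset_end
  )
  ncol_name <- .next_anchor_column[[acol]]
  if (!is.na(ncol_name) && ncol_name %in% names(trials)) {
    nxt <- trials[[ncol_name]][keep]
    bad <- !is.na(nxt) & out$t_end > nxt + 1e-9
    if (any(bad)) {
      warning(sum(bad), " `", epoch$name,
              "` window(s) extend past the next trial anchor; dropped")
      out <- out[!bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Spike train container
#'
#' @param unit_id unit identifier.
#' @param channel contact id the unit was recorded on.
#' @param spike_times non-decreasing numeric vector, seconds (session clock).
#' @return list of class `spike_train`.
#' @export
spike_train <- function(unit_id, channel, spike_times) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike times must be non-decreasing")
  structure(list(unit_id = unit_id, channel = channel,
                 spike_times = spike_times), class = "spike_train")
}

#' Read / write spike trains as `spikes.csv` (unit_id, channel, t)
#' @param path CSV path.
#' @return `load_spikes` returns a list of `spike_train`s.
#' @export
load_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "channel", "t") %in% names(df)))
  lapply(split(df, df$unit_id), function(d)
    spike_train(d$unit_id[1], d$channel[1], sort(d$t)))
}

#' @rdname load_spikes
#' @param spikes list of `spike_train`s.
#' @export
write_spikes <- function(spikes, path) {
  df <- do.call(rbind, lapply(spikes, function(s)
    data.frame(unit_id = s$unit_id, channel = s$channel, t = s$spike_times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write detected ripple events as `ripples.csv`
#' @param events a ripple event data.frame (see [detect_ripples()]).
#' @param path CSV path.
#' @return `load_ripples` returns the event data.frame.
#' @export
write_ripples <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ripples
#' @export
load_ripples <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
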