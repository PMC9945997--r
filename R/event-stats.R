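#' Ripple rates by session, epoch and condition
#'
#' For every session x epoch x (cue_location x focus x stim_size) cell the
#' rate is `n_events / (n_trials * epoch_duration)` in events/s. When events
#' carry a `channel` column the rate is computed per electrode and then
#' averaged across electrodes within the session (the repeated-measures
#' unit); events without a channel column (area-level, see [area_events()])
#' are counted directly. Cells with zero trials are absent.
#'
#' @param events event data.frame (`session`, `t_center`, optionally
#'   `channel`).
#' @param trials a `trial_table`; needs a `session_id` column for
#'   multi-session tables (defaults to the single session in `events`).
#' @param epochs named list of [epoch_definition()]s.
#' @param channels full contact-id set of the recording (so electrodes with
#'   zero events still enter the electrode average); default: the ids seen in
#'   `events`.
#' @param exclude_breaks drop fixation-break trials (default TRUE).
#' @return data.frame of class `ripple_rate_table`: `session`, `epoch`,
#'   `cue_location`, `focus`, `stim_size`, `n_trials`, `n_events`, `rate`.
#' @export
epoch_condition_rates <- function(events, trials, epochs = canonical_epochs(),
                                  channels = NULL, exclude_breaks = TRUE) {
  if (!"session_id" %in% names(trials))
    trials$session_id <- if (nrow(events)) events$session[1] else "session"
  if (exclude_breaks) trials <- trials[!trials$is_break, , drop = FALSE]
  per_channel <- "channel" %in% names(events)
  if (per_channel && is.null(channels))
    channels <- sort(unique(events$channel))
  out <- NULL
  for (ses in unique(trials$session_id)) {
    ev_s <- events[events$session == ses, , drop = FALSE]
    tr_s <- trials[trials$session_id == ses, , drop = FALSE]
    cells <- unique(tr_s[, c("cue_location", "focus", "stim_size")])
    for (ep in epochs) for (k in seq_len(nrow(cells))) {
      sel <- tr_s$cue_location == cells$cue_location[k] &
             tr_s$focus == cells$focus[k] &
             tr_s$stim_size == cells$stim_size[k]
      win <- epoch_windows(tr_s[sel, , drop = FALSE], ep)
      if (!nrow(win)) next
      total_t <- sum(win$t_end - win$t_start)
      inwin <- rep(FALSE, nrow(ev_s))
      for (w in seq_len(nrow(win)))
        inwin <- inwin | (ev_s$t_center >= win$t_start[w] &
                          ev_s$t_center <= win$t_end[w])
      n_ev <- sum(inwin)
      rate <- if (per_channel) {
        counts <- table(factor(ev_s$channel[inwin], levels = channels))
        mean(as.numeric(counts) / total_t)
      } else n_ev / total_t
      out <- rbind(out, data.frame(
        session = ses, epoch = ep$name,
        cue_location = cells$cue_location[k], focus = cells$focus[k],
        stim_size = cells$stim_size[k], n_trials = nrow(win),
        n_events = n_ev, rate = rate))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("ripple_rate_table", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank comparison of rates across sessions
#'
#' Collapses a rate table to one value per session x level of `factor`
#' (averaging over the remaining condition cells), forms session-paired
#' differences and runs a two-sided signed-rank test. Zero differences are
#' dropped; the exact null distribution is used for fewer than 20 non-zero
#' pairs.
#'
#' @param table a `ripple_rate_table` (or any data.frame with `session`,
#'   `rate` and the factor column).
#' @param factor_name `"stim_size"`, `"cue_location"` or `"focus"`.
#' @param epoch optional epoch name to restrict to.
#' @return list: `statistic` (V), `p.value`, `n` (non-zero pairs),
#'   `level_means` (named mean rate per level).
#' @export
compare_rates_paired <- function(table, factor_name = "stim_size",
                                 epoch = NULL) {
  if (!is.null(epoch)) table <- table[table$epoch == epoch, , drop = FALSE]
  f <- table[[factor_name]]
  lev <- levels(factor(f))
  if (length(lev) != 2) stop("`", factor_name, "` must have two levels")
  agg <- stats::aggregate(rate ~ session + f2,
                          data = data.frame(rate = table$rate,
                                            session = table$session,
                                            f2 = f),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "session", timevar = "f2",
                         direction = "wide")
  x <- wide[[paste0("rate.", lev[1])]]
  y <- wide[[paste0("rate.", lev[2])]]
  ok <- stats::complete.cases(x, y)
  d <- (y - x)[ok]
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p.value = 1, n = 0,
                level_means = c(mean(x, na.rm = TRUE), mean(y, na.rm = TRUE))))
  wt <- stats::wilcox.test(d, exact = length(d) < 20, correct = TRUE)
  lm_ <- c(mean(x[ok]), mean(y[ok])); names(lm_) <- lev
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(d), level_means = lm_)
}

#' Three-factor repeated-measures ANOVA on ripple rates
#'
#' Sessions are the repeated-measures unit; the design is the complete
#' 2 x 2 x 2 within-session factorial (cue_location x focus x stim_size) for
#' one epoch. Sessions with incomplete cells are excluded listwise. Each
#' effect is tested against its own session-by-effect error stratum
#' (`aov` with `Error(session/(A*B*C))`).
#'
#' @param table a `ripple_rate_table`.
#' @param epoch epoch name (default `"sustained"`).
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p` for the three
#'   main effects, the three pairwise interactions and the three-way
#'   interaction; attribute `n_sessions`.
#' @export
rm_anova3 <- function(table, epoch = "sustained") {
  d <- table[table$epoch == epoch, , drop = FALSE]
  d$session <- factor(d$session)
  complete <- tapply(seq_len(nrow(d)), d$session, function(i) {
    cells <- unique(d[i, c("cue_location", "focus", "stim_size")])
    nrow(cells) == 8 && length(i) == 8
  })
  keep <- names(complete)[unlist(complete)]
  if (length(keep) < nrow(stats::na.omit(data.frame(x = unique(d$session)))))
    if (length(keep) < length(unique(d$session)))
      message(length(unique(d$session)) - length(keep),
              " session(s) with incomplete cells excluded")
  d <- d[d$session %in% keep, , drop = FALSE]
  if (length(keep) < 3) stop("RM-ANOVA needs at least 3 complete sessions")
  d$session <- droplevels(d$session)
  fit <- stats::aov(rate ~ cue_location * focus * stim_size +
                      Error(session / (cue_location * focus * stim_size)),
                    data = d)
  sm <- summary(fit)
  out <- NULL
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    for (r in seq_along(rn)) {
      if (rn[r] == "Residuals" || is.na(tab[r, "F value"])) next
      out <- rbind(out, data.frame(
        effect = rn[r], F = tab[r, "F value"], df1 = tab[r, "Df"],
        df2 = tab[nrow(tab), "Df"], p = tab[r, "Pr(>F)"]))
    }
  }
  rownames(out) <- NULL
  attr(out, "n_sessions") <- length(keep)
  out
}

#' Post hoc signed-rank tests with FDR correction
#'
#' Runs a two-sided Wilcoxon signed-rank test for each declared paired
#' contrast and adjusts the p-values with Benjamini-Hochberg within the
#' contrast family.
#'
#' @param contrasts named list; each element is a list with paired numeric
#'   vectors `x` and `y`.
#' @return data.frame with `contrast`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc_signrank_fdr <- function(contrasts) {
  res <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    d <- ct$y - ct$x
    d <- d[!is.na(d) & d != 0]
    if (!length(d)) return(data.frame(contrast = nm, statistic = NA_real_,
                                      p_raw = 1))
    wt <- stats::wilcox.test(d, exact = length(d) < 20)
    data.frame(contrast = nm, statistic = unname(wt$statistic),
               p_raw = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  out
}

# assign area-level events to trials of an epoch; returns events with
# trial_id and time relative to the epoch window start
.events_in_epoch <- function(events, trials, epoch) {
  win <- epoch_windows(trials, epoch)
  out <- NULL
  for (k in seq_len(nrow(win))) {
    hit <- events$t_center >= win$t_start[k] & events$t_center <= win$t_end[k]
    if (!any(hit)) next
    ev <- events[hit, , drop = FALSE]
    ev$trial_id <- win$trial_id[k]
    ev$t_rel <- ev$t_center - win$t_start[k]
    out <- rbind(out, ev)
  }
  out
}

#' Shuffle-predictor-corrected cross-area correlogram
#'
#' Histograms the lags `t_B - t_A` (positive = area A leads) over all
#' same-trial event pairs within an epoch, subtracts a shuffle predictor (the
#' mean histogram after randomly permuting the trial assignment of the B
#' events, which removes stimulus-locked covariation), and splits the area
#' under the corrected correlogram at lag zero. Bins are centred on zero; the
#' central bin contributes half to each side. When both event sets carry
#' channels, a per-channel-pair AUC asymmetry (lead minus lag) is computed
#' and tested with a Wilcoxon signed-rank test.
#'
#' @param events_a,events_b event data.frames (`t_center`, optionally
#'   `channel`).
#' @param trials a `trial_table` (at least 2 trials with events).
#' @param epoch an [epoch_definition()] restricting the pairing
#'   (default: sustained).
#' @param bin_ms,max_lag_ms histogram geometry, ms.
#' @param n_shuffles trial permutations for the predictor.
#' @param pair_test compute the per-channel-pair asymmetry test.
#' @return list of class `cross_correlogram`: `lags` (bin centres, ms),
#'   `raw`, `predictor`, `corrected`, `auc_lead`, `auc_lag`, `n_pairs`, and
#'   (optionally) `pair_auc_diff`, `pair_test`.
#' @export
cross_area_correlogram <- function(events_a, events_b, trials,
                                   epoch = canonical_epochs()$sustained,
                                   bin_ms = 5, max_lag_ms = 200,
                                   n_shuffles = 100, pair_test = FALSE) {
  ea <- .events_in_epoch(events_a, trials, epoch)
  eb <- .events_in_epoch(events_b, trials, epoch)
  if (is.null(ea) || is.null(eb)) stop("no events inside the epoch windows")
  # the permutation pool must be every trial with an epoch window (not just
  # trials that happen to contain events), or the predictor is biased high
  trial_ids <- epoch_windows(trials, epoch)$trial_id
  if (length(trial_ids) < 2)
    stop("shuffle predictor undefined with fewer than 2 trials")
  breaks <- seq(-max_lag_ms - bin_ms / 2, max_lag_ms + bin_ms / 2, by = bin_ms)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  hist_pairs <- function(a, b) {
    lag <- numeric(0)
    for (tr in intersect(unique(a$trial_id), unique(b$trial_id)))
      lag <- c(lag, as.vector(outer(b$t_rel[b$trial_id == tr],
                                    a$t_rel[a$trial_id == tr], `-`)) * 1000)
    lag <- lag[lag >= breaks[1] & lag <= breaks[length(breaks)]]
    graphics::hist(lag, breaks = breaks, plot = FALSE)$counts
  }
  raw <- hist_pairs(ea, eb)
  pred <- matrix(0, n_shuffles, length(centers))
  for (s in seq_len(n_shuffles)) {
    perm <- stats::setNames(sample(trial_ids), trial_ids)
    ebs <- eb
    ebs$trial_id <- unname(perm[as.character(eb$trial_id)])
    pred[s, ] <- hist_pairs(ea, ebs)
  }
  predictor <- colMeans(pred)
  corrected <- raw - predictor
  split_auc <- function(h) {
    mid <- h[centers == 0] / 2
    c(lead = sum(h[centers > 0]) + mid, lag = sum(h[centers < 0]) + mid)
  }
  auc <- split_auc(corrected)
  res <- list(lags = centers, raw = raw, predictor = predictor,
              corrected = corrected, auc_lead = unname(auc["lead"]),
              auc_lag = unname(auc["lag"]), n_pairs = sum(raw))
  if (pair_test && "channel" %in% names(ea) && "channel" %in% names(eb)) {
    diffs <- numeric(0)
    for (ca in unique(ea$channel)) for (cb in unique(eb$channel)) {
      ha <- ea[ea$channel == ca, , drop = FALSE]
      hb <- eb[eb$channel == cb, , drop = FALSE]
      if (!nrow(ha) || !nrow(hb)) next
      rawp <- hist_pairs(ha, hb)
      if (sum(rawp) == 0) next
      predp <- matrix(0, max(10, n_shuffles %/% 5), length(centers))
      for (s in seq_len(nrow(predp))) {
        perm <- stats::setNames(sample(trial_ids), trial_ids)
        hbs <- hb
        hbs$trial_id <- unname(perm[as.character(hb$trial_id)])
        predp[s, ] <- hist_pairs(ha, hbs)
      }
      aucp <- split_auc(rawp - colMeans(predp))
      diffs <- c(diffs, aucp["lead"] - aucp["lag"])
    }
    res$pair_auc_diff <- unname(diffs)
    d <- diffs[diffs != 0]
    res$pair_test <- if (length(d))
      { wt <- stats::wilcox.test(d, exact = length(d) < 20)
        list(statistic = unname(wt$statistic), p.value = wt$p.value,
             n_pairs = length(d)) } else NULL
  }
  class(res) <- "cross_correlogram"
  res
}

#' Ripple cooccurrence probability between areas
#'
#' Among trials that contain at least one area-A ripple inside the epoch
#' window, the fraction that also contain an area-B ripple in the same
#' window.
#'
#' @param events_a,events_b area-level event data.frames (`t_center`).
#' @param trials a `trial_table`.
#' @param epoch an [epoch_definition()].
#' @return list: `probability`, `n_a_trials`, `n_joint_trials`.
#' @export
cooccurrence_probability <- function(events_a, events_b, trials,
                                     epoch = canonical_epochs()$sustained) {
  win <- epoch_windows(trials, epoch)
  has_ev <- function(ev, k)
    any(ev$t_center >= win$t_start[k] & ev$t_center <= win$t_end[k])
  a_tr <- vapply(seq_len(nrow(win)), function(k) has_ev(events_a, k),
                 logical(1))
  b_tr <- vapply(seq_len(nrow(win)), function(k) has_ev(events_b, k),
                 logical(1))
  n_a <- sum(a_tr); n_joint <- sum(a_tr & b_tr)
  list(probability = if (n_a) n_joint / n_a else 0,
       n_a_trials = n_a, n_joint_trials = n_joint)
}

#' Ripple-locked spike rate with matched-control resampling
#'
#' Peri-event histogram of a unit's firing around ripple centres, and a
#' control histogram built from condition-matched, ripple-free trials at the
#' same within-trial time: for each event a control trial with the same
#' condition combination and no ripple is drawn (with replacement), the
#' event's offset from stimulus onset is transplanted into it, and spikes of
#' the same unit are histogrammed there. The control draw is repeated
#' `n_control_reps` times and averaged.
#'
#' @param spikes list of `spike_train`s (one per contact).
#' @param events event data.frame with `t_center`, `channel`, `trial_id`.
#' @param trials a `trial_table` with condition columns and `t_stim_on`.
#' @param window_ms total window width centred on the event, ms (200 gives
#'   +/-100 ms; 50 gives the +/-25 ms core window).
#' @param bin_ms histogram bin, ms.
#' @param n_control_reps control resampling repetitions.
#' @param ripple_trials optional vector of trial ids to treat as ripple
#'   trials (excluded from the control pool); default: trials in `events`.
#' @return list: `lags_ms` (bin centres), `ripple_rate`, `ripple_sem`,
#'   `control_rate`, `control_sem` (Hz), `n_events`, `n_dropped` (events
#'   without an eligible matched trial).
#' @export
ripple_locked_spike_rate <- function(spikes, events, trials, window_ms = 200,
                                     bin_ms = 10, n_control_reps = 10,
                                     ripple_trials = NULL) {
  half_s <- window_ms / 2000
  breaks <- seq(-half_s, half_s, by = bin_ms / 1000)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  unit_by_channel <- stats::setNames(spikes,
    vapply(spikes, function(s) as.character(s$channel), character(1)))
  if (is.null(ripple_trials)) ripple_trials <- unique(events$trial_id)
  psth_at <- function(unit, t_c) {
    st <- unit$spike_times
    rel <- st[st >= t_c - half_s & st <= t_c + half_s] - t_c
    graphics::hist(rel, breaks = breaks, plot = FALSE)$counts /
      (bin_ms / 1000)
  }
  cond_key <- function(tr_rows)
    paste(tr_rows$cue_location, tr_rows$focus, tr_rows$stim_size)
  trials$.key <- cond_key(trials)
  rip <- matrix(NA_real_, nrow(events), length(centers))
  ctl <- matrix(NA_real_, nrow(events), length(centers))
  dropped <- 0
  for (e in seq_len(nrow(events))) {
    unit <- unit_by_channel[[as.character(events$channel[e])]]
    if (is.null(unit)) { dropped <- dropped + 1; next }
    rip[e, ] <- psth_at(unit, events$t_center[e])
    tr <- trials[trials$trial_id == events$trial_id[e], , drop = FALSE]
    if (!nrow(tr)) { dropped <- dropped + 1; next }
    offset <- events$t_center[e] - tr$t_stim_on[1]
    pool <- trials[trials$.key == tr$.key[1] &
                   !(trials$trial_id %in% ripple_trials) &
                   !is.na(trials$t_stim_on), , drop = FALSE]
    if (!nrow(pool)) { dropped <- dropped + 1; next }
    acc <- numeric(length(centers))
    for (r in seq_len(n_control_reps)) {
      ct <- pool[sample.int(nrow(pool), 1), , drop = FALSE]
      acc <- acc + psth_at(unit, ct$t_stim_on[1] + offset)
    }
    ctl[e, ] <- acc / n_control_reps
  }
  if (dropped) message(dropped, " event(s) without an eligible matched trial")
  ok <- stats::complete.cases(rip) & stats::complete.cases(ctl)
  sem <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
  list(lags_ms = centers * 1000,
       ripple_rate = colMeans(rip[ok, , drop = FALSE]),
       ripple_sem = sem(rip[ok, , drop = FALSE]),
       control_rate = colMeans(ctl[ok, , drop = FALSE]),
       control_sem = sem(ctl[ok, , drop = FALSE]),
       n_events = sum(ok), n_dropped = dropped)
}

#' Spike-triggered average of the LFP
#'
#' Average LFP segment around spike times; the standard harness for checking
#' spike leakage into the LFP (a sharp biphasic deflection at lag zero that
#' vanishes after leakage removal).
#'
#' @param sig LFP signal vector.
#' @param fs sampling rate, Hz.
#' @param spike_times seconds, same clock as `t0`.
#' @param window_ms window total width, ms.
#' @param t0 session time of `sig[1]`.
#' @return list: `lags_ms`, `sta`, `n_spikes`.
#' @export
spike_triggered_average <- function(sig, fs, spike_times, window_ms = 50,
                                    t0 = 0) {
  half_n <- round(window_ms / 2000 * fs)
  acc <- numeric(2 * half_n + 1); used <- 0
  for (t_s in spike_times) {
    ic <- round((t_s - t0) * fs) + 1
    if (ic - half_n < 1 || ic + half_n > length(sig)) next
    acc <- acc + sig[(ic - half_n):(ic + half_n)]
    used <- used + 1
  }
  list(lags_ms = (-half_n:half_n) / fs * 1000,
       sta = if (used) acc / used else acc * NA, n_spikes = used)
}

#' Mixed-effects model of a trial-level response
#'
#' Fits `response ~ cue_location + ripple + focus + stim_size +
#' (1 | session)` by REML with treatment coding (reference levels: cue away,
#' no ripple, narrow focus, large stimulus, so coefficient signs follow the
#' conventional effect directions), followed by a Type-III F-table with
#' Satterthwaite degrees of freedom. A singular random-intercept fit falls
#' back to the pooled linear model with a warning; `random = FALSE` forces
#' the pooled model (whose coefficients equal OLS).
#'
#' @param data data.frame with `session`, `cue_location` (away/RF), `ripple`
#'   (factor, reference `"no"`), `focus` (narrow/wide), `stim_size`
#'   (large/small) and the response column.
#' @param response `"rt_ms"` or `"firing_rate"` (any numeric column name).
#' @param random fit the session random intercept (default TRUE).
#' @return list of class `model_result`: `coefficients` (data.frame with
#'   `estimate`, `se`), `anova` (effect, F, df1, df2, p), `ranef_var`
#'   (session intercept variance), `sigma`, `singular`, `pooled`, `model`.
#' @export
fit_mixed_model <- function(data, response = "rt_ms", random = TRUE) {
  if (length(unique(data$session)) < 2 && random)
    stop("mixed model needs at least 2 sessions")
  data$session <- factor(data$session)
  data$cue_location <- stats::relevel(factor(data$cue_location), "away")
  rip_lev <- unique(as.character(data$ripple))
  ref <- if ("no" %in% rip_lev) "no" else sort(rip_lev)[1]
  data$ripple <- stats::relevel(factor(data$ripple), ref)
  data$focus <- stats::relevel(factor(data$focus), "narrow")
  data$stim_size <- stats::relevel(factor(data$stim_size), "large")
  fml <- stats::as.formula(paste(
    response, "~ cue_location + ripple + focus + stim_size"))
  pooled <- FALSE; singular <- FALSE; ranef_var <- 0
  if (random) {
    fml_mm <- stats::update(fml, . ~ . + (1 | session))
    fit <- lmerTest::lmer(fml_mm, data = data, REML = TRUE)
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("singular random-effect variance; falling back to pooled model")
      fit <- stats::lm(fml, data = data); pooled <- TRUE
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      ranef_var <- vc$vcov[vc$grp == "session"]
    }
  } else {
    fit <- stats::lm(fml, data = data); pooled <- TRUE
  }
  if (pooled) {
    co <- summary(fit)$coefficients
    an <- stats::anova(fit)
    an <- an[rownames(an) != "Residuals", , drop = FALSE]
    atab <- data.frame(effect = rownames(an), F = an$`F value`,
                       df1 = an$Df, df2 = stats::df.residual(fit),
                       p = an$`Pr(>F)`)
  } else {
    co <- summary(fit)$coefficients
    an <- stats::anova(fit, type = 3)
    atab <- data.frame(effect = rownames(an), F = an$`F value`,
                       df1 = an$NumDF, df2 = an$DenDF, p = an$`Pr(>F)`)
  }
  rownames(atab) <- NULL
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], row.names = NULL),
    anova = atab, ranef_var = ranef_var,
    sigma = stats::sigma(fit), singular = singular, pooled = pooled,
    model = fit), class = "model_result")
}
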