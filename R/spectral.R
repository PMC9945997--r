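#' Short-time Fourier spectrogram
#'
#' Hanning-tapered, mean-subtracted sliding-window power spectrum. With the
#' default 200-ms window and 5-ms step the frequency resolution is 5 Hz.
#' Power is normalized so that the sum over one-sided frequency bins equals
#' the taper-weighted variance of the window (Parseval). An optional
#' baseline interval yields a relative spectrogram (each spectrum divided by
#' the mean spectrum over the baseline windows), removing the 1/f background.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param window_ms window length, ms.
#' @param step_ms hop between window centres, ms.
#' @param t0 session time of `x[1]`, seconds.
#' @param baseline optional `c(t_start, t_end)` in session time; windows whose
#'   centres fall inside define the baseline spectrum.
#' @return list of class `spectrogram`: `times` (window centres, s), `freqs`
#'   (Hz), `power` (n_freq x n_time), `scale` (`"linear"` or `"relative"`).
#' @export
stft_spectrogram <- function(x, fs, window_ms = 200, step_ms = 5, t0 = 0,
                             baseline = NULL) {
  win_n <- round(window_ms / 1000 * fs)
  if (length(x) < win_n) stop("signal shorter than the analysis window")
  step_n <- max(1L, round(step_ms / 1000 * fs))
  starts <- seq(1L, length(x) - win_n + 1L, by = step_n)
  spec0 <- .window_spectrum(x[seq_len(win_n)], fs)
  power <- matrix(0, length(spec0$freq), length(starts))
  power[, 1] <- spec0$power
  for (k in seq_along(starts)[-1])
    power[, k] <- .window_spectrum(x[starts[k]:(starts[k] + win_n - 1L)],
                                   fs)$power
  times <- t0 + (starts - 1 + (win_n - 1) / 2) / fs
  scale <- "linear"
  if (!is.null(baseline)) {
    inb <- times >= baseline[1] & times <= baseline[2]
    if (!any(inb)) stop("baseline interval contains no window centres")
    base <- rowMeans(power[, inb, drop = FALSE])
    power <- power / (base + 1e-15)
    scale <- "relative"
  }
  structure(list(times = times, freqs = spec0$freq, power = power,
                 scale = scale), class = "spectrogram")
}

#' Morlet-wavelet centre frequencies
#'
#' `n_freq` logarithmically spaced frequencies from `f_lo` to `f_hi`:
#' `f_k = f_lo * (f_hi / f_lo)^(k / (n_freq - 1))`.
#'
#' @param f_lo,f_hi range, Hz.
#' @param n_freq number of frequencies (>= 2).
#' @return numeric vector.
#' @export
morlet_freqs <- function(f_lo = 3, f_hi = 250, n_freq = 40) {
  if (n_freq < 2) stop("`n_freq` must be at least 2")
  f_lo * (f_hi / f_lo)^((seq_len(n_freq) - 1) / (n_freq - 1))
}

#' Complex-Morlet wavelet spectrogram
#'
#' Convolves the signal with complex Morlet wavelets in the frequency domain
#' (FFT of the signal times a Gaussian frequency-domain kernel, inverse FFT)
#' and returns squared magnitude per centre frequency and sample. Centre
#' frequencies are logarithmically spaced; wavelet width is `n_cycles` cycles
#' at every centre frequency.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi frequency range, Hz (`f_hi < fs / 2`).
#' @param n_freq number of centre frequencies.
#' @param n_cycles wavelet width, cycles.
#' @param t0 session time of `x[1]`.
#' @return list of class `spectrogram` with `times`, `freqs`,
#'   `power` (n_freq x n_samples), `scale = "linear"`.
#' @export
wavelet_spectrogram <- function(x, fs, f_lo = 3, f_hi = 250, n_freq = 40,
                                n_cycles = 7, t0 = 0) {
  if (f_hi >= fs / 2) stop("`f_hi` must be below Nyquist")
  freqs <- morlet_freqs(f_lo, f_hi, n_freq)
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  fgrid <- c(seq(0, floor(nfft / 2)),
             seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  power <- matrix(0, n_freq, n)
  for (k in seq_len(n_freq)) {
    f0 <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f0)
    # analytic kernel: Gaussian on positive frequencies only, peak gain 2 so
    # a unit-amplitude sinusoid at f0 has |y| ~ 1
    H <- 2 * exp(-0.5 * (2 * pi * (fgrid - f0) * sigma_t)^2)
    H[fgrid < 0] <- 0
    y <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
    power[k, ] <- Mod(y)^2
  }
  structure(list(times = t0 + (seq_len(n) - 1) / fs, freqs = freqs,
                 power = power, scale = "linear"), class = "spectrogram")
}

# mean wavelet power per frequency in a window around each event; channels of
# a recording are averaged. Returns n_events x n_freq (NA rows = event window
# did not fit).
.event_power_matrix <- function(rec, event_times, window_ms, f_lo, f_hi,
                                n_freq, n_cycles) {
  half_n <- round(window_ms / 1000 * rec$fs / 2)
  acc <- NULL
  for (ch in seq_len(nrow(rec$data))) {
    sp <- wavelet_spectrogram(rec$data[ch, ], rec$fs, f_lo, f_hi, n_freq,
                              n_cycles, t0 = rec$t0)
    m <- matrix(NA_real_, length(event_times), n_freq)
    for (e in seq_along(event_times)) {
      ic <- round((event_times[e] - rec$t0) * rec$fs) + 1
      a <- ic - half_n; b <- ic + half_n
      if (a < 1 || b > ncol(sp$power)) next
      m[e, ] <- rowMeans(sp$power[, a:b, drop = FALSE])
    }
    acc <- if (is.null(acc)) m else acc + m
  }
  acc / nrow(rec$data)
}

.fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Ripple-triggered power-power comodulogram
#'
#' For each trigger event, wavelet power is averaged over a window centred on
#' the event in both the trigger-area and target-area recordings, giving one
#' power value per frequency per event. The comodulogram cell
#' `(f_trigger, f_target)` is the Pearson correlation, across events, of
#' trigger power at `f_trigger` with target power at `f_target`; the matrix
#' is Fisher z-transformed. Events are also divided into `n_splits` disjoint
#' groups whose per-group z values serve as samples for
#' [correct_and_test()].
#'
#' @param trigger_events numeric vector of event centre times (s), or a
#'   data.frame with a `t_center` column.
#' @param trigger_rec,target_rec [laminar_recording()]s covering the events.
#' @param window_ms power-averaging window, ms.
#' @param f_lo,f_hi,n_freq,n_cycles wavelet parameters
#'   (see [wavelet_spectrogram()]).
#' @param n_splits number of event groups for the inferential samples.
#' @param channels optional subset of channel rows to use (e.g. one laminar
#'   compartment); default all.
#' @return list of class `comodulogram`: `trigger_freqs`, `target_freqs`,
#'   `r`, `z`, `z_samples` (n_splits x n_freq x n_freq), `n_events`.
#' @export
ripple_triggered_comodulogram <- function(trigger_events, trigger_rec,
                                          target_rec, window_ms = 200,
                                          f_lo = 3, f_hi = 250, n_freq = 40,
                                          n_cycles = 7, n_splits = 10,
                                          channels = NULL) {
  times <- if (is.data.frame(trigger_events)) trigger_events$t_center
           else as.numeric(trigger_events)
  if (!is.null(channels)) {
    trigger_rec$data <- trigger_rec$data[channels, , drop = FALSE]
    target_rec$data <- target_rec$data[channels, , drop = FALSE]
  }
  ptrig <- .event_power_matrix(trigger_rec, times, window_ms, f_lo, f_hi,
                               n_freq, n_cycles)
  ptarg <- .event_power_matrix(target_rec, times, window_ms, f_lo, f_hi,
                               n_freq, n_cycles)
  ok <- stats::complete.cases(ptrig) & stats::complete.cases(ptarg)
  if (sum(ok) < 10)
    stop("insufficient data: fewer than 10 trigger events with valid windows")
  ptrig <- ptrig[ok, , drop = FALSE]
  ptarg <- ptarg[ok, , drop = FALSE]
  n_ev <- nrow(ptrig)
  r <- stats::cor(ptrig, ptarg)
  n_splits <- max(2L, min(n_splits, floor(n_ev / 3)))
  split_id <- rep(seq_len(n_splits), length.out = n_ev)
  zs <- array(NA_real_, c(n_splits, n_freq, n_freq))
  for (s in seq_len(n_splits)) {
    idx <- split_id == s
    zs[s, , ] <- .fisher_z(suppressWarnings(
      stats::cor(ptrig[idx, , drop = FALSE], ptarg[idx, , drop = FALSE])))
  }
  freqs <- morlet_freqs(f_lo, f_hi, n_freq)
  structure(list(trigger_freqs = freqs, target_freqs = freqs, r = r,
                 z = .fisher_z(r), z_samples = zs, n_events = n_ev),
            class = "comodulogram")
}

#' Baseline-correct and test a comodulogram
#'
#' Compares a ripple-triggered comodulogram against a control comodulogram
#' built from condition- and time-matched ripple-free windows. Each cell is
#' tested with a Welch t-test between the event-group Fisher-z samples of the
#' two comodulograms; Benjamini-Hochberg correction runs across all
#' frequency-pair cells.
#'
#' @param comod,control_comod `comodulogram` objects of identical shape.
#' @param alpha significance level for the FDR mask.
#' @return `comod` with added `z_diff` (comod z minus control z), `p`,
#'   `p_adj` and logical `sig_mask` matrices.
#' @export
correct_and_test <- function(comod, control_comod, alpha = 0.05) {
  if (!identical(dim(comod$r), dim(control_comod$r)))
    stop("comodulogram and control have different shapes")
  nf1 <- length(comod$trigger_freqs); nf2 <- length(comod$target_freqs)
  p <- matrix(NA_real_, nf1, nf2)
  for (i in seq_len(nf1)) for (j in seq_len(nf2)) {
    a <- comod$z_samples[, i, j]; b <- control_comod$z_samples[, i, j]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) { p[i, j] <- 1; next }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p[i, j] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      p[i, j] <- stats::t.test(a, b)$p.value
    }
  }
  p_adj <- matrix(stats::p.adjust(as.vector(p), method = "BH"), nf1, nf2)
  comod$z_diff <- comod$z - control_comod$z
  comod$p <- p
  comod$p_adj <- p_adj
  comod$sig_mask <- p_adj < alpha
  comod
}
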