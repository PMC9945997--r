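# Independent brute-force implementations used as oracles.

# exhaustive run-length scan for the dual-threshold candidate logic
oracle_scan <- function(env, fs, cfg) {
  above <- env > cfg$z_candidate
  events <- list()
  i <- 1L
  n <- length(env)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      events[[length(events) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  merged <- list()
  for (e in events) {
    if (length(merged) &&
        (e[1] - merged[[length(merged)]][2] - 1) / fs * 1000 <
          cfg$merge_gap_ms)
      merged[[length(merged)]][2] <- e[2]
    else merged[[length(merged) + 1L]] <- e
  }
  keep <- Filter(function(e) {
    d <- (e[2] - e[1] + 1) / fs * 1000
    d >= cfg$dur_min_ms && d <= cfg$dur_max_ms &&
      max(env[e[1]:e[2]]) > cfg$z_confirm
  }, merged)
  if (!length(keep))
    return(data.frame(i_start = integer(), i_end = integer()))
  data.frame(i_start = vapply(keep, `[`, 1, 1),
             i_end = vapply(keep, `[`, 1, 2))
}

# smooth synthetic z-trace for property tests of the candidate logic
random_env <- function(n, seed, scale = 3) {
  set.seed(seed)
  x <- stats::filter(rnorm(n), rep(1 / 12, 12), circular = TRUE)
  as.numeric(x / sd(x) * scale)
}

# step-up Benjamini-Hochberg written independently of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# closed-form OLS via the normal equations
oracle_ols <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# exact two-sided signed-rank p for tiny n by enumerating sign patterns
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# event-time generator: Poisson events inside epoch windows (no LFP)
poisson_epoch_events <- function(trials, epoch, rate, seed) {
  set.seed(seed)
  win <- epoch_windows(trials, epoch)
  out <- NULL
  for (k in seq_len(nrow(win))) {
    n <- rpois(1, rate * (win$t_end[k] - win$t_start[k]))
    if (!n) next
    out <- rbind(out, data.frame(
      t_center = runif(n, win$t_start[k], win$t_end[k])))
  }
  if (is.null(out)) data.frame(t_center = numeric()) else out
}
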