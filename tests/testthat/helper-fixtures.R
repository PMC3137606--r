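# Shared fixtures.  The two simulated cohorts are expensive, so they are
# built once per test run and cached for all test files.

.fixture_cache <- new.env(parent = emptyenv())

#' Default 10-subject study (the calibration/round-trip cohort)
default_study <- function() {
  if (is.null(.fixture_cache$study)) {
    cfg <- uco_sim_config(n_subjects = 10, seed = 1)
    .fixture_cache$study <- cohort_study(cfg)
  }
  .fixture_cache$study
}

#' 30-subject cohort used for the onset lead-time correlation
detector_study <- function() {
  if (is.null(.fixture_cache$study30)) {
    cfg <- uco_sim_config(n_subjects = 30, seed = 5, baseline_minutes = 20)
    .fixture_cache$study30 <- cohort_study(cfg)
  }
  .fixture_cache$study30
}

#' Noiseless cosine pulse waveform: systolic peaks exactly 60/bpm apart
pulse_trace <- function(bpm, dur_s = 60, fs = 1000, mean_mmHg = 45,
                        amp_mmHg = 10) {
  t <- seq(0, dur_s, by = 1 / fs)
  signal_trace(mean_mmHg + amp_mmHg * cos(2 * pi * bpm / 60 * t),
               fs = fs, units = "mmHg")
}

#' White Gaussian noise band-limited to [0, edge] Hz by hard FFT truncation
#' (independent of the package's trapezoid-shaped generator)
band_noise <- function(n, fs, edge, sd_target = 1) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f > edge] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  y * sd_target / sd(y)
}

#' Constant-value derived series on a regular grid
const_series <- function(value, kind, from = 0, to = 600, by = 4) {
  tt <- seq(from + by / 2, to, by = by)
  derived_series(tt, rep(value, length(tt)), kind)
}

#' Synthetic feature table for the onset detectors
make_features <- function(n, period_s = 120, spike = rep(FALSE, n),
                          hypo = rep(FALSE, n), t0 = 0) {
  start <- t0 + (seq_len(n) - 1) * period_s
  data.frame(
    subject_id = "T01", series = "severe",
    start_s = start, end_s = start + 60,
    dec_sef_peak = ifelse(spike, 23, 10),
    interdec_trough_sef = ifelse(spike, 3, 9),
    abp_at_nadir = ifelse(hypo, 40, 60),
    pre30_abp = 45,
    stringsAsFactors = FALSE
  )
}

#' Independent permutation oracle: plain loop, permuting condition labels
#' within each subject
oracle_perm_p <- function(mat, stat_fun, n_perm) {
  obs <- stat_fun(mat)
  hits <- 0
  for (b in seq_len(n_perm)) {
    pm <- mat
    for (r in seq_len(nrow(mat))) pm[r, ] <- pm[r, sample(ncol(mat))]
    if (stat_fun(pm) >= obs - 1e-12) hits <- hits + 1
  }
  (1 + hits) / (n_perm + 1)
}

#' Textbook Friedman chi-square (continuous data, no ties)
oracle_friedman <- function(mat) {
  r <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

#' Textbook one-way repeated-measures F statistic
oracle_rm_F <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  g <- mean(mat)
  ssc <- n * sum((colMeans(mat) - g)^2)
  sss <- k * sum((rowMeans(mat) - g)^2)
  sse <- sum((mat - g)^2) - ssc - sss
  (ssc / (k - 1)) / (sse / ((k - 1) * (n - 1)))
}

#' Independent brute-force SEF oracle: cumulative power scan over the Welch
#' spectrum of one window, written as a plain per-window loop
oracle_sef <- function(x, fs = 100, window_s = 4, q = 0.95, band = c(0.3, 30)) {
  nwin <- window_s * fs
  nseg <- 2 * fs
  hop <- nseg / 2
  nwindows <- floor(length(x) / nwin)
  out <- numeric(nwindows)
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  for (w in seq_len(nwindows)) {
    seg0 <- (w - 1) * nwin
    psum <- 0
    nsegs <- 0
    for (s0 in seq(seg0, seg0 + nwin - nseg, by = hop)) {
      seg <- x[(s0 + 1):(s0 + nseg)] * h
      p <- Mod(stats::fft(seg))^2
      p <- p[1:(nseg / 2 + 1)]
      p[2:(nseg / 2)] <- 2 * p[2:(nseg / 2)]
      psum <- psum + p
      nsegs <- nsegs + 1
    }
    p <- psum / nsegs
    freqs <- (0:(nseg / 2)) * fs / nseg
    sel <- freqs >= band[1] & freqs <= band[2]
    fb <- freqs[sel]; pb <- p[sel]
    cum <- cumsum(pb)
    out[w] <- fb[which(cum >= q * cum[length(cum)])[1]]
  }
  out
}
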