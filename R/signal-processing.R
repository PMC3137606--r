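# Signal processing: raw traces -> derived series.
#
# ABP is the instantaneous arterial-minus-amniotic pressure difference.
# ECOG is band-passed 0.3-30 Hz with a zero-phase 4th-order Butterworth and
# resampled to 100 Hz; amplitude and 95% spectral edge frequency are then
# computed over non-overlapping 4-s windows.  FHR is triggered from
# systolic peaks of the pulsatile ABP waveform.

FS_ECOG_PROCESSED <- 100

#' Arterial blood pressure as arterial minus amniotic pressure
#'
#' @param arterial,amniotic `signal_trace` objects sharing the same sampling
#'   rate and clock (overlapping extent).
#' @return A `signal_trace` (mmHg) over the common extent.
#' @examples
#' a <- signal_trace(rep(55, 1000), fs = 100, units = "mmHg")
#' b <- signal_trace(rep(10, 1000), fs = 100, units = "mmHg")
#' mean(compute_abp(a, b)$values)  # 45
#' @export
compute_abp <- function(arterial, amniotic) {
  stopifnot(inherits(arterial, "signal_trace"), inherits(amniotic, "signal_trace"))
  if (arterial$fs != amniotic$fs) {
    stop("compute_abp: arterial and amniotic sampling rates differ")
  }
  t0 <- max(arterial$t0, amniotic$t0)
  t1 <- min(arterial$t0 + trace_duration(arterial),
            amniotic$t0 + trace_duration(amniotic))
  if (t1 <= t0) stop("compute_abp: traces have disjoint extents")
  fs <- arterial$fs
  ia <- round((t0 - arterial$t0) * fs) + 1L
  ib <- round((t0 - amniotic$t0) * fs) + 1L
  n <- floor((t1 - t0) * fs)
  signal_trace(arterial$values[ia:(ia + n - 1L)] - amniotic$values[ib:(ib + n - 1L)],
               fs = fs, t0 = t0, units = "mmHg")
}

#' Exact resampling of a band-limited signal via FFT truncation
#'
#' Output length is `floor(n * fs_out / fs_in)`.  Intended for signals
#' already band-limited below `fs_out / 2` (here the 30 Hz ECOG band).
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates, `fs_out <= fs_in`.
#' @return Numeric vector at `fs_out`.
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  stopifnot(fs_out <= fs_in)
  if (fs_out == fs_in) return(x)
  n <- length(x)
  m_target <- floor(n * fs_out / fs_in)
  # reduce fs_out/fs_in to p/q, then reflection-pad to an FFT-friendly
  # length divisible by q so the resampled length is integral
  a <- round(fs_out * 1000); b <- round(fs_in * 1000)
  g <- function(u, v) if (v == 0) u else Recall(v, u %% v)
  d <- g(a, b)
  p <- a / d; q <- b / d
  np <- q * nextn(ceiling(n / q), c(2, 3, 5))
  if (np > n) {
    pad <- x[pmax(1L, n - seq_len(np - n))]  # reflect the tail
    x <- c(x, pad)
  }
  m <- np * p / q
  X <- fft(x)
  keep <- min(floor((m - 1) / 2), floor((np - 1) / 2))
  Y <- complex(m)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(m - keep + 1):m] <- X[(np - keep + 1):np]
  }
  (Re(fft(Y, inverse = TRUE)) / np)[seq_len(m_target)]
}

#' Preprocess raw ECOG: zero-phase 0.3-30 Hz band-pass, then 100 Hz
#'
#' A 4th-order Butterworth band-pass is applied forward-backward
#' (zero phase), after which the trace is resampled to exactly 100 Hz.
#'
#' @param ecog A `signal_trace` with `fs >= 200` Hz.
#' @return A `signal_trace` at 100 Hz; length `floor(n * 100 / fs)`.
#' @export
preprocess_ecog <- function(ecog) {
  stopifnot(inherits(ecog, "signal_trace"))
  if (ecog$fs < 200) {
    stop("preprocess_ecog: fs must be >= 200 Hz to honour the 30 Hz band before decimation")
  }
  filt <- signal::butter(4, ECOG_BAND / (ecog$fs / 2), type = "pass")
  y <- signal::filtfilt(filt, ecog$values)
  y <- resample_fft(y, ecog$fs, FS_ECOG_PROCESSED)
  signal_trace(y, fs = FS_ECOG_PROCESSED, t0 = ecog$t0, units = ecog$units)
}

#' Welch power spectra for consecutive non-overlapping windows
#'
#' Each `window_s` window is split into 2-s Hann segments at 50% overlap
#' whose periodograms are averaged.  Returns the matrix of one-sided power
#' spectra (rows = frequency bins) and the bin frequencies.
#' @noRd
welch_windows <- function(x, fs, window_s, seg_s = 2) {
  nwin <- window_s * fs
  nseg <- seg_s * fs
  hop <- nseg %/% 2L
  nwindows <- floor(length(x) / nwin)
  if (nwindows == 0L) {
    return(list(power = matrix(0, 0, 0), freqs = numeric(0), n = 0L))
  }
  nper <- (nwin - nseg) %/% hop + 1L              # segments per window
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  # gather all segments of all windows into one matrix, one mvfft call
  win_start <- rep((seq_len(nwindows) - 1L) * nwin, each = nper)
  seg_start <- win_start + rep((seq_len(nper) - 1L) * hop, times = nwindows)
  idx <- outer(seq_len(nseg), seg_start, `+`)
  segm <- matrix(x[idx], nrow = nseg) * h
  P <- Mod(mvfft(segm))^2
  half <- nseg %/% 2L
  P <- P[seq_len(half + 1L), , drop = FALSE]
  P[2:half, ] <- 2 * P[2:half, ]                  # one-sided
  # average the segments belonging to each window
  grp <- rep(seq_len(nwindows), each = nper)
  power <- t(rowsum(t(P), grp)) / nper
  list(power = power, freqs = (0:half) * fs / nseg, n = nwindows)
}

#' 4-s amplitude and 95% spectral edge frequency series
#'
#' Over consecutive non-overlapping windows of processed (100 Hz) ECOG,
#' computes: `SEF95`, the smallest frequency below which at least
#' `sef_quantile` of the Welch spectral power in the 0.3-30 Hz analysis band
#' lies; and `AMP`, the amplitude as the 97.5th minus 2.5th percentile of
#' the windowed signal (a robust peak-to-peak estimate).  A trailing
#' partial window is discarded; windows are stamped at their centers.
#'
#' @param ecog A `signal_trace` at 100 Hz.
#' @param window_s Window length in seconds (default 4; `window_s * fs`
#'   must be integral).
#' @param sef_quantile Spectral power quantile (default 0.95).
#' @param band Analysis band in Hz for the SEF cumulative power.
#' @return A list with `derived_series` elements `amp` and `sef`.
#' @export
window_features <- function(ecog, window_s = 4, sef_quantile = 0.95,
                            band = ECOG_BAND) {
  stopifnot(inherits(ecog, "signal_trace"))
  if (abs(ecog$fs - FS_ECOG_PROCESSED) > 1e-9) {
    stop("window_features: expected ECOG at 100 Hz (run preprocess_ecog first)")
  }
  nwin <- window_s * ecog$fs
  if (abs(nwin - round(nwin)) > 1e-9) {
    stop("window_features: window_s * fs must be integral")
  }
  nwin <- as.integer(round(nwin))
  nwindows <- floor(length(ecog$values) / nwin)
  if (nwindows == 0L) {
    return(list(amp = derived_series(numeric(0), numeric(0), "AMP_uV"),
                sef = derived_series(numeric(0), numeric(0), "SEF95_Hz")))
  }
  wl <- welch_windows(ecog$values, ecog$fs, window_s)
  in_band <- wl$freqs >= band[1] & wl$freqs <= band[2]
  fb <- wl$freqs[in_band]
  pb <- wl$power[in_band, , drop = FALSE]
  cum <- apply(pb, 2, cumsum)
  tot <- cum[nrow(cum), ]
  sef <- fb[max.col(t(cum >= rep(sef_quantile, nrow(cum)) %o% tot),
                    ties.method = "first")]
  xm <- matrix(ecog$values[seq_len(nwindows * nwin)], nrow = nwin)
  qs <- apply(xm, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  amp <- qs[2, ] - qs[1, ]
  centers <- ecog$t0 + ((seq_len(nwindows) - 1L) + 0.5) * window_s
  list(amp = derived_series(centers, amp, "AMP_uV"),
       sef = derived_series(centers, sef, "SEF95_Hz"))
}

#' Pulse-averaged ABP series
#'
#' Moving-average (default 3 s) of the raw pulsatile ABP, subsampled to
#' `fs_out`; used for event-locked pressure features, which are
#' mean-pressure excursions rather than systolic extremes.
#'
#' @param abp A `signal_trace` of pulsatile ABP.
#' @param smooth_s Moving-average length in seconds.
#' @param fs_out Output rate in Hz.
#' @return A `derived_series` of kind `ABP_mmHg`.
#' @export
smooth_abp <- function(abp, smooth_s = 3, fs_out = 10) {
  stopifnot(inherits(abp, "signal_trace"))
  m <- rolling_mean(abp$values, round(smooth_s * abp$fs))
  step <- max(1L, round(abp$fs / fs_out))
  idx <- seq(1L, length(m), by = step)
  derived_series(abp$t0 + (idx - 1L) / abp$fs, m[idx], "ABP_mmHg")
}

#' Fetal heart rate from arterial-pressure systolic peaks
#'
#' Systolic peaks are located on the detrended pulsatile waveform (local
#' maxima above a prominence threshold, sub-sample refined by parabolic
#' interpolation); instantaneous FHR is `60 / (t[i+1] - t[i])` bpm stamped
#' at the earlier beat.  Implausible beats (interval outside
#' `[0.12, 1.5]` s or more than 1.75x the local median interval) are
#' rejected and linearly interpolated across, flagged in the result.  Spans
#' of 10 s or more without detectable peaks are left as gaps.
#'
#' @param abp A pulsatile ABP `signal_trace`.
#' @param min_prominence Minimum detrended peak height, mmHg (default 5).
#' @return A `derived_series` of kind `FHR_bpm` with `flags` marking
#'   interpolated beats.
#' @export
extract_fhr <- function(abp, min_prominence = 5) {
  stopifnot(inherits(abp, "signal_trace"))
  fs <- abp$fs
  x <- abp$values
  z <- x - rolling_mean(x, round(fs))          # remove slow pressure path
  n <- length(z)
  if (n < 3L) stop("extract_fhr: trace too short")
  is_pk <- c(FALSE, z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n], FALSE)
  pk <- which(is_pk & z > min_prominence)
  # the detrending window is truncated at the trace edges; drop peaks there
  pk <- pk[pk > fs & pk <= n - fs]
  if (length(pk) < 3L) stop("extract_fhr: no detectable systolic peaks")
  # enforce a 0.12 s refractory period, keeping the larger peak
  repeat {
    close <- which(diff(pk) < 0.12 * fs)
    if (!length(close)) break
    drop <- ifelse(z[pk[close]] >= z[pk[close + 1L]], close + 1L, close)
    pk <- pk[-unique(drop)]
  }
  # parabolic sub-sample refinement of peak times
  i <- pk[pk > 1L & pk < n]
  denom <- z[i - 1L] - 2 * z[i] + z[i + 1L]
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (z[i - 1L] - z[i + 1L]) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  tpk <- abp$t0 + (i - 1L + delta) / fs
  iv <- diff(tpk)
  med <- stats::runmed(iv, k = min(21L, 2L * (length(iv) %/% 2L) + 1L))
  bad <- iv < 0.12 | iv > 1.5 | iv > 1.75 * med
  fhr <- 60 / iv
  times <- tpk[-length(tpk)]
  flags <- bad
  if (any(bad) && any(!bad)) {
    fhr[bad] <- approx(times[!bad], fhr[!bad], xout = times[bad], rule = 2)$y
  }
  # gaps >= 10 s stay gaps: drop interpolated beats inside long silent spans
  long_gap <- bad & iv >= 10
  keep <- !long_gap
  derived_series(times[keep], fhr[keep], "FHR_bpm", flags = flags[keep])
}
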