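# Spectral shapes for synthetic ECOG and their calibration against the
# processing pipeline (band-pass filtfilt + FFT resampling + Welch SEF).
#
# Each ECOG regime (behavioural state, deceleration suppression, SEF burst,
# inter-deceleration floor) is coloured Gaussian noise with a trapezoidal
# power spectrum: flat between `lo` and `edge`, cosine roll-off above the
# edge (width 25% of the edge) and cosine roll-up below `lo`.  The edge is
# chosen so that the *pipeline-observed* 95% spectral edge frequency equals
# the requested target, accounting for the zero-phase Butterworth band-pass
# (applied twice, hence |H|^4 on power) and the Welch bin quantisation.

ECOG_BAND <- c(0.3, 30)   # analysis band, Hz
SEF_BIN_HZ <- 0.5         # Welch resolution with 2-s segments

#' Trapezoidal power spectral density, unit passband height
#' @noRd
trapezoid_psd <- function(f, edge, lo = ECOG_BAND[1]) {
  w <- 0.25 * edge
  s <- numeric(length(f))
  up <- f < lo
  s[up] <- 0.5 * (1 - cos(pi * f[up] / lo))
  flat <- f >= lo & f <= edge
  s[flat] <- 1
  roll <- f > edge & f < edge + w
  s[roll] <- 0.5 * (1 + cos(pi * (f[roll] - edge) / w))
  s
}

# Per-process cache of filter responses and calibration curves, keyed by
# the raw sampling rate.
.spectra_cache <- new.env(parent = emptyenv())

#' Squared-magnitude response (single pass) of the ECOG band-pass at `f` Hz
#' @noRd
bandpass_power_response <- function(f, fs) {
  filt <- signal::butter(4, ECOG_BAND / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  num <- den <- rep(0 + 0i, length(z))
  for (k in seq_along(filt$b)) num <- num + filt$b[k] * z^(k - 1)
  for (k in seq_along(filt$a)) den <- den + filt$a[k] * z^(k - 1)
  Mod(num / den)^2
}

#' Calibration tables for a given raw sampling rate
#'
#' Precomputes, on a dense frequency grid, the pipeline power weight
#' W(f) = |H_bp(f)|^4 and, over a grid of trapezoid edges, the SEF the
#' pipeline would observe and the amplitude attenuation factor.  Returns
#' interpolators `edge_for_sef()` and `attenuation(edge)`.
#' @noRd
spectra_calibration <- function(fs) {
  key <- sprintf("fs%g", fs)
  if (!is.null(.spectra_cache[[key]])) return(.spectra_cache[[key]])
  fgrid <- seq(0, min(50, fs / 2), by = 0.01)
  W <- bandpass_power_response(fgrid, fs)^2      # filtfilt: |H|^4 on power
  in_band <- fgrid >= ECOG_BAND[1] & fgrid <= ECOG_BAND[2]
  edges <- seq(1, 34, by = 0.2)
  obs_sef <- attn <- numeric(length(edges))
  for (i in seq_along(edges)) {
    s <- trapezoid_psd(fgrid, edges[i])
    g <- s * W
    gb <- g[in_band]
    cum <- cumsum(gb)
    fstar <- fgrid[in_band][match(TRUE, cum >= 0.95 * cum[length(cum)])]
    # Welch bins quantise upward by ~half a bin on average
    obs_sef[i] <- fstar + SEF_BIN_HZ / 2
    attn[i] <- sqrt(sum(g) / sum(s))
  }
  # keep the strictly increasing part for inversion (the observed SEF
  # saturates once the trapezoid roll-off leaves the analysis band)
  mono <- c(TRUE, diff(obs_sef) > 1e-6) & cummax(obs_sef) <= obs_sef
  cal <- list(
    fgrid = fgrid, W = W,
    edge_for_sef = stats::approxfun(obs_sef[mono], edges[mono], rule = 2),
    attenuation = stats::approxfun(edges, attn, rule = 2),
    observed_sef = stats::approxfun(edges, obs_sef, rule = 2)
  )
  .spectra_cache[[key]] <- cal
  cal
}

#' Analytic 95% spectral edge of a power spectrum
#'
#' Numerically integrates a power spectral density over the ECOG analysis
#' band and returns the frequency below which `q` of the band power lies.
#' Used both by the simulator's calibration and as an independent reference
#' for what the SEF of a specified spectrum should be.
#'
#' @param psd A function of frequency (Hz) returning power density.
#' @param q Power quantile (default 0.95).
#' @param band Frequency band over which power is accumulated.
#' @param df Integration step in Hz.
#' @return Frequency in Hz.
#' @export
analytic_sef <- function(psd, q = 0.95, band = ECOG_BAND, df = 0.005) {
  f <- seq(band[1], band[2], by = df)
  p <- psd(f)
  cum <- cumsum(p)
  f[match(TRUE, cum >= q * cum[length(cum)])]
}

#' Gaussian noise with a trapezoidal spectrum, by FFT shaping
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param edge Trapezoid edge frequency, Hz.
#' @param sigma Target standard deviation of the generated signal.
#' @return Numeric vector of length `n`.
#' @noRd
shaped_noise <- function(n, fs, edge, sigma) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(rnorm(1L, 0, sigma))
  m <- nextn(n, c(2, 3, 5))          # FFT-friendly length, truncated below
  x <- rnorm(m)
  f <- (seq_len(m) - 1L) * fs / m
  f <- pmin(f, fs - f)
  a <- sqrt(trapezoid_psd(f, edge))
  y <- Re(fft(fft(x) * a, inverse = TRUE)) / m
  scale <- sqrt(mean(a^2))
  if (scale <= 0) return(numeric(n))
  y[seq_len(n)] * sigma / scale
}

#' Assemble a piecewise-stationary shaped-noise signal with crossfades
#'
#' `segs` is a data frame with columns `i0`, `i1` (1-based inclusive sample
#' ranges, contiguous and covering 1..n), `edge`, `sigma`.  Adjacent
#' segments are blended with an equal-power sine/cosine crossfade of
#' `fade_s` seconds so no broadband discontinuity is introduced.
#' @noRd
assemble_shaped <- function(n, fs, segs, fade_s = 0.5) {
  out <- numeric(n)
  L <- round(fade_s * fs)
  nseg <- nrow(segs)
  for (k in seq_len(nseg)) {
    i0 <- segs$i0[k]; i1 <- segs$i1[k]
    # extend into the neighbours by L/2 for the crossfade
    e0 <- if (k > 1L) max(1L, i0 - L %/% 2L) else i0
    e1 <- if (k < nseg) min(n, i1 + L %/% 2L) else i1
    seg <- shaped_noise(e1 - e0 + 1L, fs, segs$edge[k], segs$sigma[k])
    env <- rep(1, length(seg))
    if (k > 1L) {
      nf <- i0 + L %/% 2L - e0          # fade-in length
      if (nf > 1L) env[seq_len(nf)] <- sin(seq(0, pi / 2, length.out = nf))^1
    }
    if (k < nseg) {
      nf <- e1 - (i1 - L %/% 2L) + 1L   # fade-out length
      if (nf > 1L) {
        idx <- (length(seg) - nf + 1L):length(seg)
        env[idx] <- cos(seq(0, pi / 2, length.out = nf))^1
      }
    }
    out[e0:e1] <- out[e0:e1] + seg * env
  }
  out
}
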