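# Signal operators: ABP differencing, ECOG preprocessing, windowed
# amplitude / spectral-edge features, and systolic-peak FHR extraction.

test_that("ABP is the pointwise arterial-minus-amniotic difference", {
  fs <- 200
  amn <- signal_trace(10 + sin(seq(0, 20, by = 1 / fs)), fs = fs, units = "mmHg")
  art_same <- amn
  expect_equal(compute_abp(art_same, amn)$values,
               rep(0, length(amn$values)))
  art <- signal_trace(amn$values + 45, fs = fs, units = "mmHg")
  abp <- compute_abp(art, amn)
  expect_equal(abp$values, rep(45, length(amn$values)))
  expect_identical(abp$units, "mmHg")

  other_fs <- signal_trace(amn$values, fs = 100)
  expect_error(compute_abp(art, other_fs), "sampling rates")
  late <- signal_trace(amn$values, fs = fs, t0 = 1e5)
  expect_error(compute_abp(art, late), "disjoint")
})

test_that("ECOG preprocessing passes the band, removes DC, rejects 60 Hz", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  sine10 <- signal_trace(sin(2 * pi * 10 * t), fs = fs, units = "uV")
  out <- preprocess_ecog(sine10)
  expect_equal(out$fs, 100)
  expect_equal(length(out$values), floor(length(sine10$values) * 100 / fs))
  mid <- out$values[500:2500]
  expect_lt(abs(sqrt(2 * mean(mid^2)) - 1), 0.01)  # pass-band amplitude within 1%

  dc <- preprocess_ecog(signal_trace(rep(5, length(t)) + sin(2 * pi * 5 * t),
                                     fs = fs, units = "uV"))
  expect_lt(abs(mean(dc$values[500:2500])), 0.05)

  s60 <- preprocess_ecog(signal_trace(sin(2 * pi * 60 * t), fs = fs, units = "uV"))
  rms_out <- sqrt(mean(s60$values[500:2500]^2))
  rms_in <- sqrt(0.5)
  expect_lt(20 * log10(rms_out / rms_in), -20)  # >= 20 dB attenuation

  expect_error(preprocess_ecog(signal_trace(rnorm(1000), fs = 100)), "200 Hz")
})

test_that("SEF95 matches analytic values for line and flat spectra", {
  fs <- 100
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  sine <- signal_trace(sin(2 * pi * 10 * t), fs = fs, units = "uV")
  wf <- window_features(sine)
  expect_true(all(abs(wf$sef$values - 10) <= 0.5))   # all power at one line

  set.seed(401)
  wn <- signal_trace(band_noise(fs * 1200, fs, edge = 20, sd_target = 10),
                     fs = fs, units = "uV")
  wfn <- window_features(wn)
  # flat spectrum on [0, 20]: 95% point at 0.3 + 0.95 * (20 - 0.3) = 19.0
  expect_lt(abs(mean(wfn$sef$values) - 19.0), 0.5)

  short <- signal_trace(rnorm(100), fs = fs, units = "uV")
  wfe <- window_features(short)
  expect_length(wfe$sef$values, 0)                   # sub-window trace: empty
})

test_that("SEF95 equals the brute-force cumulative-power oracle per window", {
  fs <- 100
  set.seed(402)
  edges <- runif(25, 5, 28)
  n_per <- 4 * 4 * fs                                # 4 windows per edge
  x <- unlist(lapply(edges, function(e) band_noise(n_per, fs, e)))
  tr <- signal_trace(x, fs = fs, units = "uV")
  wf <- window_features(tr)
  ora <- oracle_sef(x, fs = fs)
  expect_length(wf$sef$values, 100)
  expect_true(all(abs(wf$sef$values - ora) <= 0.5))  # within one bin
})

test_that("amplitude scales linearly and SEF95 is scale-invariant", {
  fs <- 100
  set.seed(403)
  x <- band_noise(fs * 400, fs, edge = 15, sd_target = 20)
  a <- window_features(signal_trace(x, fs = fs, units = "uV"))
  b <- window_features(signal_trace(3 * x, fs = fs, units = "uV"))
  expect_equal(b$amp$values, 3 * a$amp$values, tolerance = 1e-12)
  expect_identical(b$sef$values, a$sef$values)
})

test_that("SEF95 never decreases when spectral power moves upward", {
  fs <- 100
  set.seed(404)
  base <- band_noise(fs * 200, fs, edge = 8)
  sef_of <- function(x) mean(window_features(
    signal_trace(x, fs = fs, units = "uV"))$sef$values)
  prev <- sef_of(base)
  for (e in c(12, 16, 20, 24)) {
    cur <- sef_of(band_noise(fs * 200, fs, edge = e))
    expect_gt(cur, prev)
    prev <- cur
  }
  # time compression of one signal shifts all power up
  x <- band_noise(fs * 400, fs, edge = 10)
  compressed <- x[seq(1, length(x), by = 2)]        # same fs label: 2x frequency
  expect_gt(sef_of(compressed), sef_of(x))
})

test_that("FHR extraction is exact on noiseless pulse trains", {
  for (bpm in seq(60, 240, by = 30)) {
    fhr <- extract_fhr(pulse_trace(bpm, dur_s = 60))
    expect_true(all(abs(fhr$values - bpm) <= 0.5),
                label = sprintf("%d bpm train", bpm))
  }
})

test_that("a missing beat is interpolated and flagged; long gaps stay gaps", {
  fs <- 1000
  tr <- pulse_trace(120, dur_s = 30, fs = fs)
  # remove one beat by flattening one pulse period around t = 15 s
  kill <- which(trace_times(tr) > 14.75 & trace_times(tr) < 15.25)
  tr$values[kill] <- 45
  fhr <- extract_fhr(tr)
  bad <- which(fhr$flags)
  expect_length(bad, 1L)
  # away from the artifact every beat is exact; the artifact's immediate
  # neighbours may be slightly distorted by the local detrending
  clean <- abs(fhr$times - 15) > 2 & !fhr$flags
  expect_true(all(abs(fhr$values[clean] - 120) <= 0.5))
  expect_true(abs(fhr$values[bad] - 120) <= 5)       # interpolated across

  # silent span >= 10 s: flagged as a gap, not an error
  tr2 <- pulse_trace(120, dur_s = 40, fs = fs)
  kill2 <- which(trace_times(tr2) > 14 & trace_times(tr2) < 26)
  tr2$values[kill2] <- 45
  fhr2 <- extract_fhr(tr2)
  expect_true(max(diff(fhr2$times)) >= 10)           # gap survives
  ok <- abs(fhr2$values - 120) <= 0.5
  expect_gt(mean(ok), 0.9)
})

test_that("pulse-averaged ABP removes pulsatility but keeps the mean path", {
  tr <- pulse_trace(150, dur_s = 120, fs = 250, mean_mmHg = 50, amp_mmHg = 10)
  sm <- smooth_abp(tr)
  mid <- series_window(sm, 10, 110)
  expect_lt(max(abs(mid - 50)), 0.6)
})
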