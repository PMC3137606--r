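# Event-locked feature extraction and aggregation.

# beat-time FHR series following a piecewise-linear rate profile
fhr_profile_series <- function(breaks_t, breaks_v, to = 600, step = 0.4) {
  tt <- seq(0, to, by = step)
  derived_series(tt, approx(breaks_t, breaks_v, xout = tt, rule = 2)$y, "FHR_bpm")
}

test_that("baseline summaries are means over the extent, with guards", {
  fhr <- const_series(163, "FHR_bpm", by = 0.4)
  abp <- const_series(45, "ABP_mmHg", by = 0.1)
  amp <- const_series(88, "AMP_uV")
  sef <- const_series(14.4, "SEF95_Hz")
  b <- baseline_summary(fhr, abp, amp, sef, c(0, 600))
  expect_equal(b$fhr, 163); expect_equal(b$abp, 45)
  expect_equal(b$amp, 88); expect_equal(b$sef, 14.4)
  expect_error(baseline_summary(fhr, abp, amp, sef, c(100, 100)), "empty")
  expect_warning(baseline_summary(fhr, abp, amp, sef, c(0, 300)), "10 min")
  expect_error(suppressWarnings(
    baseline_summary(fhr, abp, amp, sef, c(700, 750))), "no data")
})

test_that("a triangular deceleration yields its analytic nadir and onset", {
  # 163 -> 80 -> 163 over the occlusion [100, 160], apex at 130
  fhr <- fhr_profile_series(c(0, 100, 130, 160, 600), c(163, 163, 80, 163, 163))
  abp <- const_series(45, "ABP_mmHg", by = 0.1)
  amp <- const_series(88, "AMP_uV")
  sef <- const_series(14.4, "SEF95_Hz")
  b <- suppressWarnings(baseline_summary(fhr, abp, amp, sef, c(0, 90)))
  ev <- data.frame(series = "mild", start_s = 100, end_s = 160)
  f <- extract_event_features(ev, fhr, abp, amp, sef, b)
  expect_lt(abs(f$fhr_nadir - 80), 1)
  expect_lt(abs(f$t_nadir - 130), 0.5)
  expect_equal(f$d_fhr, b$fhr - f$fhr_nadir)       # conservation, exact
  # onset: rate crosses baseline - 15 = 148 at t = 100 + 30*(163-148)/83
  expect_lt(abs(f$dec_onset_s - (100 + 30 * 15 / 83)), 1)
})

test_that("a flat heart rate is a null event with the fallback ECOG window", {
  fhr <- const_series(163, "FHR_bpm", by = 0.4)
  abp <- const_series(45, "ABP_mmHg", by = 0.1)
  # amplitude distinguishable by window: 10 before the event, 99 inside
  tt <- seq(2, 600, by = 4)
  amp <- derived_series(tt, ifelse(tt >= 100 & tt < 160, 99, 10), "AMP_uV")
  sef <- const_series(14.4, "SEF95_Hz")
  b <- suppressWarnings(baseline_summary(fhr, abp, amp, sef, c(0, 90)))
  ev <- data.frame(series = "mild", start_s = 100, end_s = 160)
  f <- extract_event_features(ev, fhr, abp, amp, sef, b)
  expect_equal(f$fhr_nadir, 163)
  expect_equal(f$d_fhr, 0)
  expect_true(is.na(f$dec_onset_s))
  expect_equal(f$dec_amp, 99)                      # [start, start + 60) fallback
  expect_equal(f$pre30_amp, 10)                    # pre-window untouched
})

test_that("every 4-s window feeds at most one of the pre/deceleration means", {
  st <- default_study()
  f <- st$features
  # windows are half-open: [start-30, start) and [onset, onset+60) never share
  # a center; verified on the synthetic cohort via the window bookkeeping
  expect_true(all(f$dec_onset_s >= f$start_s | is.na(f$dec_onset_s)))
  expect_equal(f$d_fhr + f$fhr_nadir,
               rep(tapply(f$d_fhr + f$fhr_nadir, f$subject_id, mean)[f$subject_id],
                   1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("series summaries aggregate subjects first and ignore event order", {
  f1 <- make_features(4)
  f1$fhr_nadir <- c(80, 82, 84, 86)
  s <- series_summary(f1, columns = "fhr_nadir")
  expect_equal(s$mean, 83)
  expect_equal(s$sem, 0); expect_false(s$sem_defined)  # single subject

  f2 <- f1; f2$subject_id <- "T02"; f2$fhr_nadir <- f2$fhr_nadir + 10
  both <- rbind(f1, f2)
  s2 <- series_summary(both, columns = "fhr_nadir")
  expect_equal(s2$mean, 88)                        # mean of per-subject means
  expect_true(s2$sem_defined)
  shuffled <- both[sample(nrow(both)), ]
  expect_equal(series_summary(shuffled, columns = "fhr_nadir"), s2)
})

test_that("10-min interval summaries window events onto their sample", {
  f <- make_features(10, period_s = 120, t0 = 1000)     # events at 1000..2080
  f$dec_amp <- seq_len(10) * 10
  smp <- data.frame(time_s = c(1390, 2500, 900), pH = c(7.2, 7.1, 7.3))
  iv <- interval_summaries(f, smp)
  # sample at 1390: events starting in [790, 1390) -> events 1..4
  r1 <- iv[iv$sample_time_s == 1390, ]
  expect_equal(r1$n_events, 4)
  expect_equal(r1$dec_amp, mean(c(10, 20, 30, 40)))
  expect_equal(r1$ph, 7.2)
  # sample at 2500: events in [1900, 2500) -> events 9, 10 (start 1960, 2080)
  r2 <- iv[iv$sample_time_s == 2500, ]
  expect_equal(r2$n_events, 2)
  # sample before the series: no events, no summary
  expect_false(900 %in% iv$sample_time_s)
})

test_that("after the hypotension onset, occlusions lose the pressure rise", {
  st <- default_study()
  ok <- 0L; tot <- 0L
  for (su in st$subjects) {
    hyp <- su$truth$hypotension_onset_s
    f <- su$features
    post <- which(f$end_s >= hyp + 120)
    tot <- tot + length(post)
    ok <- ok + sum(f$abp_at_nadir[post] <= f$pre30_abp[post] + 0.5, na.rm = TRUE)
  }
  expect_gt(tot, 50)
  expect_gte(ok / tot, 0.95)
})
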