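# Synthetic cohort generator: configuration invariants, protocol
# construction, pH trajectory, cardiovascular and ECOG synthesis.

test_that("configuration invariants are enforced", {
  expect_error(uco_sim_config(fhr_nadir_mean = 170), "below")
  expect_error(uco_sim_config(abp_uco_max_mean = 40), "exceed")
  expect_error(uco_sim_config(sef_spike_peak_mean = 60), "Nyquist")
  expect_error(uco_sim_config(sef_floor_mean = 20, ecog_sef_baseline_mean = 14.4),
               "floor")
  expect_error(uco_sim_config(ph_baseline = 7.1), "spiking_onset_ph_mean")
  expect_error(uco_sim_config(fs_ecog = 100), "200 Hz")
  expect_error(uco_sim_config(nonsense_field = 1), "unknown")
})

test_that("protocol encodes the three-series schedule and the stop rule", {
  cfg <- uco_sim_config(n_subjects = 1, seed = 2, baseline_minutes = 60)
  set.seed(2)
  tr <- fetaluco:::draw_single_traits(cfg)
  tr$moderate_cross <- FALSE
  tr$t_severe_min <- 35      # latent crossing at severe minute 35
  set.seed(10)
  ph <- simulate_ph(cfg, tr)
  ev <- build_protocol(cfg, ph)

  expect_equal(sum(ev$series == "mild"), 12)       # every 5 min for 1 h
  expect_equal(sum(ev$series == "moderate"), 20)   # every 3 min for 1 h
  n_sev <- sum(ev$series == "severe")
  expect_gte(n_sev, 10); expect_lte(n_sev, 51)     # 20-100 min at 2-min spacing
  expect_true(all(ev$end_s - ev$start_s == 60))
  for (se in c("mild", "moderate", "severe")) {
    period <- c(mild = 300, moderate = 180, severe = 120)[[se]]
    expect_true(all(diff(ev$start_s[ev$series == se]) == period))
  }
  # no occlusion starts after the stop sample; stop is the first pH < 7 sample
  expect_true(all(ev$start_s < ph$stop_s))
  expect_lt(ph$samples$pH[ph$samples$time_s == ph$stop_s], 7.00)
  # latent crossing cannot come after the measured detection
  expect_lte(ph$cross_s, ph$stop_s)
})

test_that("an occlusion-free protocol yields no events; a pH that never
           crosses 7.00 is a simulation error naming the subject", {
  cfg0 <- uco_sim_config(n_subjects = 1, seed = 3, baseline_minutes = 20,
                         protocol = default_protocol()[0, ])
  set.seed(3)
  ph0 <- simulate_ph(cfg0)
  expect_equal(nrow(build_protocol(cfg0, ph0)), 0L)

  cfg <- uco_sim_config(n_subjects = 1, seed = 4, baseline_minutes = 20,
                        mild_drop = 0, moderate_drop = 0,
                        gap_recovery = c(0, 0), dip_amp = c(mild = 0, moderate = 0,
                                                            severe = 0))
  set.seed(4)
  tr <- fetaluco:::draw_single_traits(cfg)
  tr$moderate_cross <- FALSE
  tr$t_severe_min <- Inf     # degenerate dynamics: pH stays at baseline
  set.seed(4)
  ph <- simulate_ph(cfg, tr)
  expect_true(all(abs(ph$samples$pH - tr$ph_base) < 0.05))
  expect_true(is.na(ph$stop_s))
  expect_error(build_protocol(cfg, ph), "S01")
})

test_that("cohort pH trajectory matches the study conditions", {
  st <- default_study()
  smp <- st$samples
  expect_lt(abs(mean(smp$pH[smp$phase == "baseline"]) - 7.36), 0.02)
  expect_lt(abs(mean(smp$pH[smp$phase == "post_stop"]) - 6.90), 0.08)
  # pH non-increasing across each subject's severe-series samples
  for (s in split(smp, smp$subject_id)) {
    sev <- s[grepl("^severe", s$phase), ]
    if (nrow(sev) > 1) expect_true(all(diff(sev$pH) < 0.015))
  }
  # ground truth ordering: spiking onset precedes the pH 7.00 crossing
  for (su in st$subjects) {
    expect_lt(su$truth$spiking_onset_s, su$truth$cross_s)
  }
  # two-ish of ten reach the target during the moderate series
  expect_lte(sum(st$traits$moderate_cross), 4)
})

test_that("simulation is deterministic for identical config and seed", {
  cfg <- uco_sim_config(n_subjects = 1, seed = 77, baseline_minutes = 10)
  a <- simulate_subject(cfg, seed = 77)
  b <- simulate_subject(cfg, seed = 77)
  expect_identical(a$ecog$values, b$ecog$values)
  expect_identical(a$arterial$values, b$arterial$values)
  expect_identical(a$events, b$events)
  expect_identical(a$samples, b$samples)
})

test_that("noiseless cardiovascular paths round-trip through the pipeline", {
  cfg <- uco_sim_config(n_subjects = 1, seed = 5, baseline_minutes = 10)
  events <- data.frame(series = "mild", start_s = 300, end_s = 360,
                       stringsAsFactors = FALSE)
  ph_stub <- structure(list(session_end = 600), class = "ph_curve")
  truth <- list(fhr_base = 163, fhr_nadir_mean = 80, abp_base = 45,
                abp_peak = 64, hypotension_onset_s = NA, noise = FALSE)
  out <- simulate_cardio(cfg, events, ph_stub, truth)
  expect_equal(out$truth$event_fhr_nadir, 80)      # latent nadir exact
  abp_raw <- compute_abp(out$arterial, out$amniotic)
  fhr <- extract_fhr(abp_raw)
  abp <- smooth_abp(abp_raw)
  expect_lt(abs(mean(series_window(fhr, 60, 290)) - 163), 0.5)
  expect_lt(abs(min(series_window(fhr, 300, 420)) - 80), 1)
  expect_lt(abs(mean(series_window(abp, 60, 290)) - 45), 0.5)
  expect_lt(abs(max(series_window(abp, 300, 400)) - 64), 0.8)
  expect_error(simulate_cardio(cfg, events, ph_stub,
                               modifyList(truth, list(fhr_nadir_mean = 170))),
               "nadir")
})

test_that("ECOG spectra are calibrated against the analytic spectral edge", {
  fs <- 250
  cal <- fetaluco:::spectra_calibration(fs)
  set.seed(6)
  for (target in c(3, 7.5, 14.4, 23)) {
    edge <- cal$edge_for_sef(target)
    x <- fetaluco:::shaped_noise(fs * 600, fs, edge, sigma = 20)
    proc <- preprocess_ecog(signal_trace(x, fs = fs, units = "uV"))
    wf <- window_features(proc)
    # independent oracle: 95% point of the specified spectrum as seen
    # through the pipeline's squared filter response, plus half-bin offset
    f <- seq(0.3, 30, by = 0.005)
    g <- fetaluco:::trapezoid_psd(f, edge) *
      fetaluco:::bandpass_power_response(f, fs)^2
    cum <- cumsum(g)
    expected <- f[which(cum >= 0.95 * cum[length(cum)])[1]] + 0.25
    expect_lt(abs(mean(wf$sef$values) - expected), 0.5)
    expect_lt(abs(mean(wf$sef$values) - target), 0.6)
  }
})

test_that("doubling the amplitude scale doubles AMP and leaves SEF unchanged", {
  cfg <- uco_sim_config(n_subjects = 1, seed = 8, baseline_minutes = 5)
  ph_stub <- structure(list(session_end = 400,
                            trend = function(t) rep(7.36, length(t))),
                       class = "ph_curve")
  ev0 <- data.frame(series = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  tr <- list(spiking_onset_s = NA, c_amp = 1, c_sef = 1, burst_sef = 23)
  set.seed(99)
  a <- simulate_ecog(cfg, ev0, ph_stub, tr)
  set.seed(99)
  b <- simulate_ecog(cfg, ev0, ph_stub, modifyList(tr, list(c_amp = 2)))
  expect_equal(b$ecog$values, 2 * a$ecog$values, tolerance = 1e-10)
  wa <- window_features(preprocess_ecog(a$ecog))
  wb <- window_features(preprocess_ecog(b$ecog))
  expect_identical(wa$sef$values, wb$sef$values)
  expect_equal(wb$amp$values, 2 * wa$amp$values, tolerance = 1e-10)
  expect_error(simulate_ecog(cfg, ev0, ph_stub,
                             modifyList(tr, list(burst_sef = 55))),
               "Nyquist")
})

test_that("baseline ECOG calibration is recovered by the full pipeline", {
  st <- default_study()
  bt <- st$baseline_tbl
  expect_lt(abs(mean(bt$sef) - 14.4), 0.8)
  expect_lt(abs(mean(bt$amp) - 88), 26)
})
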