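# Simulation configuration for the synthetic UCO cohort.

#' Default three-series occlusion protocol
#'
#' Mild: 1-min occlusion every 5 min for 1 h; moderate: every 3 min for 1 h;
#' severe: every 2 min until measured arterial pH < 7.00.  A 10-min
#' occlusion-free period follows the mild and the moderate series.
#'
#' @return A data frame with columns `series`, `occlusion_s`, `period_s`,
#'   `duration_policy`.
#' @export
default_protocol <- function() {
  data.frame(
    series = c("mild", "moderate", "severe"),
    occlusion_s = c(60, 60, 60),
    period_s = c(300, 180, 120),
    duration_policy = c("fixed_1h", "fixed_1h", "until_ph"),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration for a synthetic UCO cohort
#'
#' Population-level calibration constants default to the cohort means the
#' pipeline is expected to recover (heart rate 163 bpm with occlusion nadir
#' 80 bpm; arterial blood pressure 45 mmHg baseline rising to 64 mmHg during
#' occlusions; ECOG amplitude 88 uV and 95% SEF 14.4 Hz at baseline, SEF
#' bursts to 23 Hz with a 3 Hz inter-deceleration floor after the spiking
#' onset; pH falling from 7.36 to below 7.00 during the severe series, with
#' the spiking onset near pH 7.24).  Between-subject spreads are the
#' population SDs implied by the reported SEMs at the reference cohort size.
#'
#' @param n_subjects Number of simulated fetuses.
#' @param seed Master RNG seed.
#' @param baseline_minutes Baseline (pre-occlusion) recording length, min.
#' @param fs_pressure,fs_ecog Synthesis rates in Hz for the pressure and raw
#'   ECOG channels (ECOG must be >= 200 Hz for the processing chain).
#' @param ... Named overrides for any other configuration entry.
#' @return An object of class `uco_sim_config` (a validated list).
#' @examples
#' cfg <- uco_sim_config(n_subjects = 2, seed = 1, baseline_minutes = 10)
#' cfg$fhr_baseline_mean
#' @export
uco_sim_config <- function(n_subjects = 10, seed = 1, baseline_minutes = 60,
                           fs_pressure = 250, fs_ecog = 250, ...) {
  cfg <- list(
    n_subjects = n_subjects, seed = seed,
    fs_pressure = fs_pressure, fs_ecog = fs_ecog,
    baseline_minutes = baseline_minutes,
    protocol = default_protocol(),
    gap_s = 600,                       # occlusion-free period after mild/moderate
    # --- cardiovascular calibration ---
    fhr_baseline_mean = 163, fhr_baseline_sd_between = 15.8,
    fhr_nadir_mean = 80, fhr_nadir_sd_between = 6.3,
    fhr_nadir_sd_event = 2.5,
    fhr_slow_sd = 3, fhr_beat_sd = 2.5,
    abp_baseline_mean = 45, abp_baseline_sd_between = 12.6,
    abp_uco_max_mean = 64, abp_rise_sd_between = 3.2,
    abp_peak_sd_event = 2, abp_noise_sd = 1,
    pulse_amp = 18,
    # --- ECOG calibration ---
    ecog_amp_baseline_mean = 88, ecog_amp_rel_sd_between = 0.40,
    ecog_sef_baseline_mean = 14.4, ecog_sef_rel_sd_between = 0.078,
    hv_sef = 7.5, hv_amp_ratio = 2.1,
    state_hv_mean_s = 300, state_lv_mean_s = 480,
    sef_spike_peak_mean = 23, sef_spike_sd_between = 4,
    sef_floor_mean = 3,
    burst_dur_range_s = c(15, 20),
    burst_amp_frac = 0.68, floor_amp_frac = 1.25, inter_amp_factor = 1.05,
    floor_len_s = 25,
    # --- acidemia trajectory ---
    ph_baseline = 7.36, ph_baseline_sd_between = 0.032,
    ph_end_severe = 6.90,
    mild_drop = 0.035, moderate_drop = 0.133,
    gap_recovery = c(0.008, 0.015),
    moderate_shape = 1.7, severe_shape = 1.2,
    severity_sdlog = 0.15,
    severe_duration_meanlog = log(30), severe_duration_sdlog = 0.4,
    severe_duration_range_min = c(18, 95),
    p_moderate_cross = 0.2,
    dip_amp = c(mild = 0.035, moderate = 0.045, severe = 0.045),
    dip_tau_s = 100,
    ph_sample_noise_sd = 0.005,
    ph_recovery_target = 7.18,
    # --- onset coupling ---
    spiking_onset_ph_mean = 7.24, spiking_onset_ph_sd = 0.06,
    hypotension_onset_ph_lag = 0.02, onset_coupling = 0.9,
    onset_ph_clip = c(7.08, 7.31),
    # --- bookkeeping ---
    max_severe_min = 180, post_stop_s = 600
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("uco_sim_config: unknown fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "uco_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg A `uco_sim_config`.
#' @return Invisibly `TRUE`; errors on violated invariants.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "uco_sim_config"))
  fail <- function(msg) stop("uco_sim_config: ", msg, call. = FALSE)
  if (cfg$n_subjects < 1) fail("n_subjects must be >= 1")
  if (cfg$fs_ecog < 200) fail("fs_ecog must be >= 200 Hz for preprocessing")
  if (cfg$baseline_minutes < 0) fail("baseline_minutes must be >= 0")
  if (!(cfg$fhr_nadir_mean < cfg$fhr_baseline_mean)) {
    fail("fhr_nadir_mean must be below fhr_baseline_mean")
  }
  if (!(cfg$abp_uco_max_mean > cfg$abp_baseline_mean)) {
    fail("abp_uco_max_mean must exceed abp_baseline_mean")
  }
  nyq <- FS_ECOG_PROCESSED / 2
  if (!(0 < cfg$sef_floor_mean && cfg$sef_floor_mean < cfg$ecog_sef_baseline_mean &&
        cfg$ecog_sef_baseline_mean < cfg$sef_spike_peak_mean &&
        cfg$sef_spike_peak_mean < nyq)) {
    fail("need 0 < sef_floor < baseline SEF < spike peak < processed Nyquist")
  }
  if (!(cfg$ph_end_severe < 7.00 && 7.00 < cfg$spiking_onset_ph_mean &&
        cfg$spiking_onset_ph_mean < cfg$ph_baseline)) {
    fail("need ph_end_severe < 7.00 < spiking_onset_ph_mean < ph_baseline")
  }
  p <- cfg$protocol
  if (nrow(p) > 0 && (any(p$occlusion_s <= 0) || any(p$period_s <= p$occlusion_s))) {
    fail("protocol periods must exceed occlusion durations")
  }
  invisible(TRUE)
}

#' Derived ECOG state parameters (LV/HF edge and state amplitudes)
#'
#' The two behavioural states are calibrated so that their occupancy-weighted
#' SEF and amplitude match the configured baseline means.
#' @noRd
state_params <- function(cfg) {
  w_hv <- cfg$state_hv_mean_s / (cfg$state_hv_mean_s + cfg$state_lv_mean_s)
  lv_sef <- (cfg$ecog_sef_baseline_mean - w_hv * cfg$hv_sef) / (1 - w_hv)
  a_lv <- cfg$ecog_amp_baseline_mean / (w_hv * cfg$hv_amp_ratio + (1 - w_hv))
  list(w_hv = w_hv, hv_sef = cfg$hv_sef, lv_sef = lv_sef,
       hv_amp = cfg$hv_amp_ratio * a_lv, lv_amp = a_lv)
}

#' Draw cohort-level subject traits (stratified across the cohort)
#' @noRd
draw_cohort_traits <- function(cfg) {
  n <- cfg$n_subjects
  z1 <- stratified_normal(n, 0, 1)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    seed = vapply(seq_len(n), function(i) child_seed(cfg$seed, i), integer(1)),
    ph_base = stratified_normal(n, cfg$ph_baseline, cfg$ph_baseline_sd_between),
    severity = stratified_lognormal(n, 0, cfg$severity_sdlog, 0.6, 1.6),
    t_severe_min = stratified_lognormal(n, cfg$severe_duration_meanlog,
                                        cfg$severe_duration_sdlog,
                                        cfg$severe_duration_range_min[1],
                                        cfg$severe_duration_range_min[2]),
    moderate_cross = runif(n) < cfg$p_moderate_cross,
    fhr_base = stratified_normal(n, cfg$fhr_baseline_mean, cfg$fhr_baseline_sd_between),
    fhr_nadir = stratified_normal(n, cfg$fhr_nadir_mean, cfg$fhr_nadir_sd_between),
    abp_base = stratified_normal(n, cfg$abp_baseline_mean, cfg$abp_baseline_sd_between),
    # occlusion peak pressure is compressed across subjects (vasoconstrictive
    # ceiling): it tracks the subject's baseline only partially
    abp_peak_dev = stratified_normal(n, 0, cfg$abp_rise_sd_between),
    c_amp = pmin(pmax(stratified_normal(n, 1, cfg$ecog_amp_rel_sd_between), 0.3), 2),
    c_sef = pmin(pmax(stratified_normal(n, 1, cfg$ecog_sef_rel_sd_between), 0.6), 1.4),
    burst_sef = pmin(pmax(stratified_normal(n, cfg$sef_spike_peak_mean,
                                            cfg$sef_spike_sd_between), 16), 27.5),
    onset_z1 = z1,
    onset_z2 = rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Draw traits for a single stand-alone subject (no cohort stratification)
#' @noRd
draw_single_traits <- function(cfg, subject_id = "S01") {
  old_n <- cfg$n_subjects
  cfg$n_subjects <- 1L
  tr <- draw_cohort_traits(cfg)
  tr$subject_id <- subject_id
  cfg$n_subjects <- old_n
  tr
}
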