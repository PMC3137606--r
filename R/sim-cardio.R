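# Cardiovascular synthesis: latent heart-rate and mean-pressure paths
# rendered as a pulsatile arterial waveform, plus the amniotic channel.
#
# Each occlusion produces a chemoreflex deceleration: after a 2-5 s delay
# the rate falls over ~15 s to a per-occlusion nadir, stays there until
# shortly after cuff release, then recovers.  Mean arterial pressure rises
# to a per-occlusion maximum; after the subject's hypotension-onset time the
# rise is not sustained and pressure at the end of the occlusion falls to or
# below the pre-occlusion level (the biphasic hypertensive-hypotensive
# pattern).  The waveform is a phase-warped asymmetric raised-cosine pulse
# riding on the mean path, so systolic peaks are unambiguous for the
# peak-triggered FHR extraction.

#' Asymmetric raised-cosine pulse shape on phase u in [0, 1)
#'
#' Fast systolic upstroke peaking at `a`, slower diastolic decay.
#' @noRd
pulse_shape <- function(u, a = 0.3) {
  u <- u %% 1
  ifelse(u < a, 0.5 * (1 - cos(pi * u / a)),
         0.5 * (1 + cos(pi * (u - a) / (1 - a))))
}

#' Simulate arterial and amniotic pressure traces for one subject
#'
#' @param cfg A `uco_sim_config`.
#' @param events Event data frame from [build_protocol()].
#' @param ph_curve A `ph_curve` (provides the session extent and, via
#'   `truth`, the hypotension onset).
#' @param truth List with at least `fhr_base`, `abp_base`, `abp_peak`,
#'   `hypotension_onset_s` (may be `NA`) and `noise` (logical; `FALSE` for
#'   noiseless latent paths).
#' @return A list: `arterial` and `amniotic` `signal_trace`s, and `truth`
#'   augmented with per-event latent `fhr_nadir` / `abp_max` values.
#' @export
simulate_cardio <- function(cfg, events, ph_curve, truth) {
  fs <- cfg$fs_pressure
  n <- ceiling(ph_curve$session_end * fs)
  tt <- (seq_len(n) - 1L) / fs
  noisy <- !isFALSE(truth$noise)
  n_ev <- nrow(events)

  if (!(truth$fhr_nadir_mean < truth$fhr_base)) {
    stop("simulate_cardio: nadir must lie below baseline FHR")
  }

  # ---- latent FHR path ----
  fhr <- rep(truth$fhr_base, n)
  dec_shape_sum <- numeric(n)
  nadirs <- numeric(n_ev)
  for (k in seq_len(n_ev)) {
    s0 <- events$start_s[k]; e0 <- events$end_s[k]
    delay <- if (noisy) runif(1, 2, 5) else 3
    hold <- if (noisy) runif(1, 2, 8) else 5
    nadirs[k] <- truth$fhr_nadir_mean +
      (if (noisy) rnorm(1, 0, cfg$fhr_nadir_sd_event) else 0)
    depth <- truth$fhr_base - nadirs[k]
    i0 <- max(1L, floor((s0 + delay) * fs) + 1L)
    i1 <- min(n, ceiling((e0 + hold + 60) * fs))
    if (i1 <= i0) next
    tl <- tt[i0:i1]
    # ramp down over ~15 s, then a slight downward tilt across the
    # occlusion so the true minimum sits at the end of the deceleration
    # ("at or shortly after the occlusion end")
    tilt <- 1 - 0.12 * pmax(e0 + hold - tl, 0) / 60
    shp <- pmin(smoothstep((tl - s0 - delay) / 15), tilt)
    rec <- tl > e0 + hold
    shp[rec] <- exp(-(tl[rec] - e0 - hold) / 12)
    dec_shape_sum[i0:i1] <- pmax(dec_shape_sum[i0:i1], shp)
    fhr[i0:i1] <- fhr[i0:i1] - depth * shp
  }
  if (noisy) {
    damp <- 1 - 0.8 * dec_shape_sum   # variability falls during decelerations
    fhr <- fhr + ou_noise(n, fs, 60, cfg$fhr_slow_sd) * damp +
      ou_noise(n, fs, 2, cfg$fhr_beat_sd) * damp
  }
  fhr <- pmax(fhr, 25)

  # ---- latent mean ABP path ----
  abp <- rep(truth$abp_base, n)
  if (noisy) abp <- abp + ou_noise(n, fs, 30, cfg$abp_noise_sd)
  peaks <- numeric(n_ev)
  hyp_on <- truth$hypotension_onset_s
  for (k in seq_len(n_ev)) {
    s0 <- events$start_s[k]; e0 <- events$end_s[k]
    peaks[k] <- truth$abp_peak +
      (if (noisy) rnorm(1, 0, cfg$abp_peak_sd_event) else 0)
    rise <- peaks[k] - truth$abp_base
    i0 <- max(1L, floor(s0 * fs) + 1L)
    i1 <- min(n, ceiling((e0 + 120) * fs))
    if (i1 <= i0) next
    tl <- tt[i0:i1]
    post_onset <- !is.na(hyp_on) && (e0 >= hyp_on)
    if (!post_onset) {
      # rounded hypertensive bump: maximum ~35 s in, easing slightly by release
      prof <- rise * smoothstep((tl - s0) / 35) *
        (1 - 0.08 * smoothstep((tl - s0 - 35) / 25))
      rec <- tl > e0
      prof[rec] <- rise * 0.92 * exp(-(tl[rec] - e0) / 20)
    } else {
      ramp <- min(1, max(0, (e0 - hyp_on) / 1200))
      sag <- 4 + 10 * ramp                     # mmHg below baseline at cuff release
      prof <- rise * smoothstep((tl - s0) / 20)
      fall <- tl > s0 + 30 & tl <= e0
      u <- (tl[fall] - s0 - 30) / (e0 - s0 - 30)
      prof[fall] <- rise + (-sag - rise) * smoothstep(u)
      rec <- tl > e0
      prof[rec] <- -sag * exp(-(tl[rec] - e0) / 30)
    }
    abp[i0:i1] <- abp[i0:i1] + prof
  }

  # ---- render waveforms ----
  phase <- cumsum(fhr / 60) / fs
  pulse <- cfg$pulse_amp * (pulse_shape(phase) - 0.5)
  amn <- rep(10, n)
  if (noisy) {
    amn <- amn + 1.2 * sin(2 * pi * tt / 900 + runif(1, 0, 2 * pi)) +
      ou_noise(n, fs, 60, 0.4)
  }
  arterial <- signal_trace(amn + abp + pulse, fs = fs, t0 = 0, units = "mmHg")
  amniotic <- signal_trace(amn, fs = fs, t0 = 0, units = "mmHg")

  truth$event_fhr_nadir <- nadirs
  truth$event_abp_max <- peaks
  list(arterial = arterial, amniotic = amniotic, truth = truth)
}
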