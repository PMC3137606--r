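# Electrocortical synthesis.
#
# ECOG is piecewise-stationary coloured noise.  Outside occlusions the
# spectrum alternates between a high-voltage/low-frequency (HV/LF) and a
# low-voltage/high-frequency (LV/HF) behavioural state (semi-Markov epochs,
# minutes long); occupancy shifts toward HV/LF as acidemia worsens.  During
# occlusions, amplitude and spectral edge are suppressed with falling pH
# (occlusion-phase SEF more strongly than inter-occlusion SEF, so the
# prior-vs-deceleration SEF difference widens with acidemia).  After the
# subject's spiking-onset time each occlusion ends with a 15-20 s
# high-frequency burst (95% SEF near the configured spike peak); the SEF
# then collapses briefly to the configured floor before partially
# recovering ahead of the next occlusion.  Spectral edges are calibrated so
# the *processing pipeline* (band-pass, resampling, Welch windows) recovers
# the configured SEF/amplitude targets.

#' Occlusion-phase SEF suppression factor as a function of pH
#' @noRd
sef_suppression_dec <- function(ph) pmin(pmax(1 - 1.8 * (7.33 - ph), 0.42), 1)

#' Inter-occlusion SEF suppression factor (much milder than the occlusion
#' phase, so the prior-vs-during SEF difference widens with acidemia)
#' @noRd
sef_suppression_inter <- function(ph) pmin(pmax(1 - 0.25 * (7.33 - ph), 0.9), 1)

#' Occlusion-phase amplitude suppression factor as a function of pH
#' @noRd
amp_suppression <- function(ph) pmin(pmax(1 - 2.15 * (7.30 - ph), 0.45), 1)

#' Draw the behavioural-state epoch sequence over the session
#' @noRd
draw_state_epochs <- function(cfg, trend, session_end) {
  t <- 0
  state <- sample(c("HV", "LV"), 1,
                  prob = c(cfg$state_hv_mean_s, cfg$state_lv_mean_s))
  t0s <- t1s <- numeric(0)
  states <- character(0)
  while (t < session_end) {
    acid <- min(max((7.34 - trend(t)) / 0.34, 0), 1)
    m <- if (state == "HV") cfg$state_hv_mean_s * (1 + 0.8 * acid)
         else cfg$state_lv_mean_s * (1 - 0.35 * acid)
    dur <- max(30, rgamma(1, shape = 4, rate = 4 / m))
    t0s <- c(t0s, t); t1s <- c(t1s, min(t + dur, session_end))
    states <- c(states, state)
    t <- t + dur
    state <- if (state == "HV") "LV" else "HV"
  }
  data.frame(t0 = t0s, t1 = t1s, state = states, stringsAsFactors = FALSE)
}

#' Simulate the raw ECOG trace for one subject
#'
#' @param cfg A `uco_sim_config`.
#' @param events Event data frame from [build_protocol()].
#' @param ph_curve A `ph_curve`.
#' @param truth List with `spiking_onset_s` (may be `NA`), `c_amp`, `c_sef`,
#'   `burst_sef`.
#' @return A list: `ecog` (`signal_trace`, uV) and `truth` augmented with the
#'   state `epochs` and per-event burst durations.
#' @export
simulate_ecog <- function(cfg, events, ph_curve, truth) {
  fs <- cfg$fs_ecog
  if (truth$burst_sef >= FS_ECOG_PROCESSED / 2) {
    stop("simulate_ecog: burst SEF at or above the processed Nyquist frequency")
  }
  session_end <- ph_curve$session_end
  n <- ceiling(session_end * fs)
  sp <- state_params(cfg)
  cal <- spectra_calibration(fs)
  epochs <- draw_state_epochs(cfg, ph_curve$trend, session_end)
  onset <- truth$spiking_onset_s
  n_ev <- nrow(events)

  # ---- overlay intervals over the background state process ----
  ov <- data.frame(t0 = numeric(0), t1 = numeric(0), type = character(0),
                   stringsAsFactors = FALSE)
  burst_dur <- rep(NA_real_, n_ev)
  add_ov <- function(t0, t1, type) {
    t1 <- min(t1, session_end)
    if (t1 > t0) ov <<- rbind(ov, data.frame(t0 = t0, t1 = t1, type = type,
                                             stringsAsFactors = FALSE))
  }
  for (k in seq_len(n_ev)) {
    s0 <- events$start_s[k]; e0 <- events$end_s[k]
    post <- !is.na(onset) && e0 >= onset
    if (post) {
      burst_dur[k] <- runif(1, cfg$burst_dur_range_s[1], cfg$burst_dur_range_s[2])
      add_ov(s0 + 5, e0 - burst_dur[k], "dec")
      add_ov(e0 - burst_dur[k], e0, "burst")
      gap_end <- if (k < n_ev) events$start_s[k + 1] + 5 else min(e0 + 180, session_end)
      fl <- min(cfg$floor_len_s, 0.4 * (gap_end - e0))
      add_ov(e0, e0 + fl, "floor")
      add_ov(e0 + fl, gap_end, "recov")
    } else {
      add_ov(s0 + 5, e0, "dec")
    }
  }

  # ---- elementary intervals ----
  bp <- sort(unique(c(0, session_end, epochs$t0, ov$t0, ov$t1)))
  bp <- bp[bp >= 0 & bp <= session_end]
  iv <- data.frame(t0 = bp[-length(bp)], t1 = bp[-1])
  iv <- iv[iv$t1 > iv$t0, , drop = FALSE]
  # merge sub-second slivers into their predecessor
  keep <- rep(TRUE, nrow(iv))
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$t1[k] - iv$t0[k] < 1) {
      prev <- max(which(keep[seq_len(k - 1L)]))
      iv$t1[prev] <- iv$t1[k]
      keep[k] <- FALSE
    }
  }
  iv <- iv[keep, , drop = FALSE]

  mid <- (iv$t0 + iv$t1) / 2
  ov_idx <- rep(NA_integer_, nrow(iv))
  if (nrow(ov)) {
    for (j in seq_len(nrow(ov))) {
      ov_idx[mid >= ov$t0[j] & mid < ov$t1[j]] <- j
    }
  }
  ep_idx <- findInterval(mid, epochs$t0)
  st <- epochs$state[pmax(1L, ep_idx)]
  ph_mid <- ph_curve$trend(mid)

  state_sef <- ifelse(st == "HV", sp$hv_sef, sp$lv_sef) * truth$c_sef
  state_amp <- ifelse(st == "HV", sp$hv_amp, sp$lv_amp) * truth$c_amp
  sef_t <- state_sef
  amp_t <- state_amp
  type <- ifelse(is.na(ov_idx), "state", ov$type[ov_idx])
  dec <- type == "dec"
  sef_t[dec] <- state_sef[dec] * sef_suppression_dec(ph_mid[dec])
  amp_t[dec] <- state_amp[dec] * amp_suppression(ph_mid[dec])
  bur <- type == "burst"
  sef_t[bur] <- truth$burst_sef
  amp_t[bur] <- cfg$burst_amp_frac * cfg$ecog_amp_baseline_mean * truth$c_amp
  flo <- type == "floor"
  sef_t[flo] <- cfg$sef_floor_mean
  amp_t[flo] <- cfg$floor_amp_frac * cfg$ecog_amp_baseline_mean * truth$c_amp
  rcv <- type == "recov"
  sef_t[rcv] <- state_sef[rcv] * sef_suppression_inter(ph_mid[rcv])
  amp_t[rcv] <- state_amp[rcv] * cfg$inter_amp_factor
  sef_t <- pmin(pmax(sef_t, 1.3), 27.5)

  edges <- cal$edge_for_sef(sef_t)
  segs <- data.frame(
    i0 = pmax(1L, floor(iv$t0 * fs) + 1L),
    i1 = pmin(n, floor(iv$t1 * fs)),
    edge = edges,
    sigma = (amp_t / 3.92) / cal$attenuation(edges)
  )
  segs <- segs[segs$i1 >= segs$i0, , drop = FALSE]
  segs$i1[nrow(segs)] <- n
  # make ranges exactly contiguous after rounding
  if (nrow(segs) > 1L) segs$i0[-1] <- head(segs$i1, -1) + 1L
  segs <- segs[segs$i1 >= segs$i0, , drop = FALSE]

  x <- assemble_shaped(n, fs, segs)
  truth$epochs <- epochs
  truth$burst_dur_s <- burst_dur
  list(ecog = signal_trace(x, fs = fs, t0 = 0, units = "uV"), truth = truth)
}
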