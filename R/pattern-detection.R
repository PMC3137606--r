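# Onset detectors for the late-acidemia response patterns.
#
# The SEF "spiking" pattern — abrupt rises of the 95% spectral edge toward
# the end of each deceleration, collapsing to a low floor between
# decelerations — was recognised visually in the original analysis.  Here
# it is operationalised per occlusion: an event is a "spike event" when its
# end-of-deceleration SEF peak reaches `spike_hz` AND the following
# inter-deceleration SEF trough falls to `floor_hz`.  Because the pattern,
# once initiated, continued to the end of every session, the detected onset
# is the first event of the earliest run of at least `persist` consecutive
# spike events that extends to the last occlusion.  The hypotension
# detector applies the same run logic to the pressure criterion (ABP at the
# FHR nadir no higher than the pre-occlusion mean).

#' Start of the persistent terminal run satisfying a per-event predicate
#' @noRd
persistent_run_start <- function(ok, persist) {
  ok[is.na(ok)] <- FALSE
  n <- length(ok)
  if (!n) return(NA_integer_)
  # length of the all-TRUE suffix
  last_false <- if (any(!ok)) max(which(!ok)) else 0L
  run_len <- n - last_false
  if (run_len >= persist) last_false + 1L else NA_integer_
}

#' Detect the SEF spiking-pattern onset
#'
#' @param features Time-ordered feature data frame for one subject, with
#'   `dec_sef_peak`, `interdec_trough_sef` and `start_s`.
#' @param spike_hz Deceleration-end SEF peak threshold, Hz (default 15).
#' @param floor_hz Inter-deceleration SEF trough threshold, Hz (default 6).
#' @param persist Minimum run length in events (default 3).
#' @return Onset time in seconds (start of the first event of the
#'   persistent run), or `NA` when the pattern is absent.
#' @export
detect_spiking_onset <- function(features, spike_hz = 15, floor_hz = 6,
                                 persist = 3) {
  if (is.null(features) || !nrow(features)) return(NA_real_)
  ok <- features$dec_sef_peak >= spike_hz &
    features$interdec_trough_sef <= floor_hz
  i <- persistent_run_start(ok, persist)
  if (is.na(i)) NA_real_ else features$start_s[i]
}

#' Detect the hypotensive pressure-response onset
#'
#' @param features Time-ordered feature data frame with `abp_at_nadir` and
#'   `pre30_abp`.
#' @param tol Tolerance in mmHg added to the pre-occlusion mean (default 0).
#' @param persist Minimum run length in events (default 3).
#' @return Onset time in seconds, or `NA` when absent.
#' @export
detect_hypotension_onset <- function(features, tol = 0, persist = 3) {
  if (is.null(features) || !nrow(features)) return(NA_real_)
  ok <- features$abp_at_nadir <= features$pre30_abp + tol
  i <- persistent_run_start(ok, persist)
  if (is.na(i)) NA_real_ else features$start_s[i]
}

#' pH context for a detected onset
#'
#' @param onset_s Onset time in seconds (may be `NA`).
#' @param samples Sample data frame with `time_s` and `pH`.
#' @return A list: `ph_at_onset` (pH of the sample closest in time to the
#'   onset; ties resolved to the earlier sample), `ph_cross_s` (time of the
#'   first sample with pH < 7.00, `NA` when never crossed), and `lead_min`
#'   (`(ph_cross_s - onset_s) / 60`).
#' @export
ph_context <- function(onset_s, samples) {
  stopifnot(nrow(samples) >= 1L)
  cross_i <- match(TRUE, samples$pH < 7.00)
  ph_cross_s <- if (is.na(cross_i)) NA_real_ else samples$time_s[cross_i]
  if (is.na(onset_s)) {
    return(list(ph_at_onset = NA_real_, ph_cross_s = ph_cross_s,
                lead_min = NA_real_))
  }
  d <- abs(samples$time_s - onset_s)
  ph_at_onset <- samples$pH[which.min(d)]   # which.min takes the earlier tie
  list(ph_at_onset = ph_at_onset, ph_cross_s = ph_cross_s,
       lead_min = if (is.na(ph_cross_s)) NA_real_ else (ph_cross_s - onset_s) / 60)
}

#' Full onset analysis for one subject
#'
#' Runs both detectors and attaches the pH context of each onset.
#'
#' @param features Time-ordered feature data frame for one subject.
#' @param samples The subject's blood-sample table.
#' @param spike_hz,floor_hz,persist,tol Detector parameters (see
#'   [detect_spiking_onset()] and [detect_hypotension_onset()]).
#' @return A one-row data frame (`OnsetResult`): onset times, pH crossing
#'   time, lead times in minutes, pH at the spiking onset, and the
#'   parameters used.
#' @export
detect_onsets <- function(features, samples, spike_hz = 15, floor_hz = 6,
                          persist = 3, tol = 0) {
  spk <- detect_spiking_onset(features, spike_hz, floor_hz, persist)
  hyp <- detect_hypotension_onset(features, tol, persist)
  ctx_s <- ph_context(spk, samples)
  ctx_h <- ph_context(hyp, samples)
  data.frame(
    subject_id = if (!is.null(features) && "subject_id" %in% names(features))
      features$subject_id[1] else NA_character_,
    spiking_onset_s = spk, hypotension_onset_s = hyp,
    ph_cross_s = ctx_s$ph_cross_s,
    spiking_lead_min = ctx_s$lead_min,
    hypotension_lead_min = ctx_h$lead_min,
    ph_at_spiking_onset = ctx_s$ph_at_onset,
    spike_hz = spike_hz, floor_hz = floor_hz, persist = persist, tol = tol,
    stringsAsFactors = FALSE
  )
}
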