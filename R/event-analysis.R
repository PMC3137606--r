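# Event-locked feature extraction: per-occlusion cardiovascular and ECOG
# metrics, per-series aggregation (subject as the unit of analysis), and
# 10-min pre-sampling interval summaries used for the pH correlations.

#' Per-subject baseline means of the derived series
#'
#' @param fhr,abp,amp,sef `derived_series` objects (`FHR_bpm`, `ABP_mmHg`,
#'   `AMP_uV`, `SEF95_Hz`).
#' @param baseline_extent Numeric `c(from, to)` in seconds; must precede the
#'   first occlusion.
#' @return A list with means `fhr`, `abp`, `amp`, `sef` and the extent.
#' @export
baseline_summary <- function(fhr, abp, amp, sef, baseline_extent) {
  from <- baseline_extent[1]; to <- baseline_extent[2]
  if (to <= from) stop("baseline_summary: empty baseline extent")
  if (to - from < 600) {
    warning("baseline_summary: baseline shorter than 10 min; computed anyway")
  }
  vals <- list(fhr = series_window(fhr, from, to),
               abp = series_window(abp, from, to),
               amp = series_window(amp, from, to),
               sef = series_window(sef, from, to))
  if (!length(vals$fhr) || !length(vals$abp)) {
    stop("baseline_summary: no data in baseline extent")
  }
  c(lapply(vals, mean), list(extent = c(from, to)))
}

#' Deceleration onset within an occlusion
#'
#' First beat time in `[start, end]` from which FHR stays below
#' `baseline - drop_bpm` for at least `sustain_s` seconds.  `NA` when the
#' criterion is never met.
#' @noRd
deceleration_onset <- function(fhr, start, end, baseline_fhr,
                               drop_bpm = 15, sustain_s = 5) {
  thr <- baseline_fhr - drop_bpm
  i_win <- which(fhr$times >= start & fhr$times <= end + sustain_s)
  below <- fhr$values[i_win] < thr
  tms <- fhr$times[i_win]
  cand <- which(below & tms <= end)
  for (i in cand) {
    span <- which(tms >= tms[i] & tms <= tms[i] + sustain_s)
    if (length(span) >= 2L && all(below[span])) return(tms[i])
  }
  NA_real_
}

#' Event-locked features for one occlusion
#'
#' Windows follow the published analysis: FHR nadir searched in
#' `[start, end + 60]` s (the nadir falls at or shortly after cuff release);
#' maximum ABP in `[start, end + abp_max_ext]`; ABP at the FHR nadir as a
#' +/-2 s average; deceleration-window ECOG means over 4-s windows whose
#' centers lie in `[deceleration onset, onset + 60)` (falling back to
#' `[start, start + 60)` when no deceleration is detected); the SEF peak as
#' the maximum window in `[end - peak_window_s, end + peak_window_s]`;
#' pre-occlusion ECOG means over `[start - 30, start)`; and the
#' inter-deceleration SEF trough as the minimum window between this
#' occlusion's end and the next occlusion's start (or `end + 120` s for the
#' last).  Delta metrics are relative to the subject's baseline (FHR, ABP)
#' or to the 30-s pre-occlusion means (ECOG), with the ECOG deltas defined
#' as "prior minus during".  Features whose windows lack more than half
#' their data are set to `NA`, never fabricated.
#'
#' @param event One-row event data frame (`start_s`, `end_s`, `series`).
#' @param fhr,abp,amp,sef Derived series for the subject.
#' @param baseline Output of [baseline_summary()].
#' @param next_start_s Start of the following occlusion (or `NA`).
#' @param onset_drop_bpm,onset_sustain_s Deceleration-onset criterion.
#' @param peak_window_s Half-width of the end-of-deceleration SEF peak
#'   search window.
#' @param abp_max_ext Seconds past occlusion end included in the ABP_max
#'   search.
#' @return A one-row data frame of features.
#' @export
extract_event_features <- function(event, fhr, abp, amp, sef, baseline,
                                   next_start_s = NA,
                                   onset_drop_bpm = 15, onset_sustain_s = 5,
                                   peak_window_s = 20, abp_max_ext = 30) {
  s0 <- event$start_s; e0 <- event$end_s
  # regular series: require at least half the window covered
  win_or_na <- function(x, lo, hi, min_frac = 0.5) {
    v <- series_window(x, lo, hi)
    if (length(x$times) > 1L) {
      step <- median(diff(x$times))
      if (length(v) * step < min_frac * (hi - lo)) return(numeric(0))
    }
    v
  }

  fv <- series_window(fhr, s0, e0 + 60)
  ft <- fhr$times[fhr$times >= s0 & fhr$times < e0 + 60]
  if (length(ft) > 1L && max(diff(c(s0, ft, e0 + 60))) > 0.5 * (e0 + 60 - s0)) {
    fv <- numeric(0)  # beat gap covering most of the window: flag missing
  }
  if (length(fv)) {
    i_min <- which.min(fv)
    fhr_nadir <- fv[i_min]
    t_nadir <- ft[i_min]
  } else {
    fhr_nadir <- NA_real_; t_nadir <- NA_real_
  }

  dec_on <- deceleration_onset(fhr, s0, e0, baseline$fhr,
                               onset_drop_bpm, onset_sustain_s)
  dw0 <- if (is.na(dec_on)) s0 else dec_on
  dw1 <- dw0 + 60

  av <- win_or_na(abp, s0, e0 + abp_max_ext)
  abp_max <- if (length(av)) max(av) else NA_real_
  abp_at_nadir <- if (!is.na(t_nadir)) {
    nv <- series_window(abp, t_nadir - 2, t_nadir + 2)
    if (length(nv)) mean(nv) else NA_real_
  } else NA_real_

  mean_or_na <- function(x, lo, hi) {
    v <- win_or_na(x, lo, hi)
    if (length(v)) mean(v) else NA_real_
  }
  dec_amp <- mean_or_na(amp, dw0, dw1)
  dec_sef <- mean_or_na(sef, dw0, dw1)
  pre30_amp <- mean_or_na(amp, s0 - 30, s0)
  pre30_sef <- mean_or_na(sef, s0 - 30, s0)
  pre30_abp <- mean_or_na(abp, s0 - 30, s0)
  pk <- series_window(sef, e0 - peak_window_s, e0 + peak_window_s)
  dec_sef_peak <- if (length(pk)) max(pk) else NA_real_
  tr_hi <- if (is.na(next_start_s)) e0 + 120 else next_start_s
  tr <- series_window(sef, e0, tr_hi)
  interdec_trough_sef <- if (length(tr)) min(tr) else NA_real_

  data.frame(
    series = event$series, start_s = s0, end_s = e0,
    fhr_nadir = fhr_nadir, t_nadir = t_nadir,
    abp_max = abp_max, abp_at_nadir = abp_at_nadir, pre30_abp = pre30_abp,
    pre30_amp = pre30_amp, pre30_sef = pre30_sef,
    dec_amp = dec_amp, dec_sef = dec_sef,
    dec_sef_peak = dec_sef_peak, interdec_trough_sef = interdec_trough_sef,
    dec_onset_s = dec_on,
    d_fhr = baseline$fhr - fhr_nadir,
    d_abp_max = abp_max - baseline$abp,
    d_abp_nadir = abp_at_nadir - baseline$abp,
    d_amp = pre30_amp - dec_amp,
    d_sef = pre30_sef - dec_sef,
    stringsAsFactors = FALSE
  )
}

#' Event features for all of a subject's occlusions
#'
#' @param events Event data frame (ordered).
#' @param fhr,abp,amp,sef Derived series.
#' @param baseline Output of [baseline_summary()].
#' @param ... Passed to [extract_event_features()].
#' @return Data frame, one row per event, with a `subject_id` column when
#'   present in `events`.
#' @export
extract_all_features <- function(events, fhr, abp, amp, sef, baseline, ...) {
  if (!nrow(events)) return(NULL)
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(k) {
    nxt <- if (k < nrow(events)) events$start_s[k + 1] else NA
    extract_event_features(events[k, ], fhr, abp, amp, sef, baseline,
                           next_start_s = nxt, ...)
  }))
  if ("subject_id" %in% names(events)) {
    out <- cbind(subject_id = events$subject_id, out)
  }
  rownames(out) <- NULL
  out
}

#' Per-series summaries with the subject as the unit of analysis
#'
#' Per-subject means are computed first; the cohort mean and SEM are then
#' taken across subjects.  With a single subject the SEM is reported as 0
#' and flagged.
#'
#' @param features Pooled feature data frame with `subject_id` and `series`.
#' @param columns Feature columns to summarise.
#' @return A data frame: `series`, `measure`, `n_subjects`, `mean`, `sem`,
#'   `sem_defined`.
#' @export
series_summary <- function(features,
                           columns = c("fhr_nadir", "abp_max", "abp_at_nadir",
                                       "d_fhr", "d_abp_max", "d_abp_nadir",
                                       "pre30_amp", "pre30_sef", "dec_amp",
                                       "dec_sef", "dec_sef_peak", "d_amp",
                                       "d_sef")) {
  stopifnot(all(c("subject_id", "series") %in% names(features)))
  out <- list()
  for (se in unique(features$series)) {
    fs <- features[features$series == se, , drop = FALSE]
    for (cl in intersect(columns, names(fs))) {
      per_subj <- tapply(fs[[cl]], fs$subject_id,
                         function(v) mean(v, na.rm = TRUE))
      per_subj <- per_subj[is.finite(per_subj)]
      n <- length(per_subj)
      out[[length(out) + 1L]] <- data.frame(
        series = se, measure = cl, n_subjects = n,
        mean = if (n) mean(per_subj) else NA_real_,
        sem = if (n > 1) sem(per_subj) else 0,
        sem_defined = n > 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' 10-minute pre-sampling interval summaries
#'
#' For each blood sample drawn during an occlusion series, averages all
#' event features over occlusions starting within the 10 minutes preceding
#' the sample, and attaches the sample's pH.  Samples with no qualifying
#' events yield no summary.
#'
#' @param features Feature data frame for one subject (time-ordered).
#' @param samples Sample data frame with `time_s`, `pH` and (optionally)
#'   `phase`.
#' @param window_s Window length before each sample (default 600 s).
#' @return Data frame of interval summaries (one row per qualifying
#'   sample), or `NULL` when none qualify.
#' @export
interval_summaries <- function(features, samples, window_s = 600) {
  if (is.null(features) || !nrow(features)) return(NULL)
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      c("start_s", "end_s", "t_nadir", "dec_onset_s"))
  out <- list()
  for (k in seq_len(nrow(samples))) {
    ts <- samples$time_s[k]
    # only samples taken during (or at the end of) an occlusion series qualify
    in_series <- any(features$start_s < ts &
                     features$start_s >= ts - max(window_s, 1200))
    sel <- features$start_s >= ts - window_s & features$start_s < ts
    if (!in_series || !any(sel)) next
    row <- as.data.frame(lapply(features[sel, num_cols, drop = FALSE],
                                function(v) mean(v, na.rm = TRUE)))
    row$n_events <- sum(sel)
    row$sample_time_s <- ts
    row$ph <- samples$pH[k]
    if ("subject_id" %in% names(features)) {
      row <- cbind(subject_id = features$subject_id[1], row)
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
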