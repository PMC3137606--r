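# End-to-end orchestration: simulate -> process -> event analysis ->
# onset detection -> statistics/report, per subject and per cohort.

#' Analysis parameters for the processing pipeline
#'
#' @param window_s ECOG feature window length, s.
#' @param sef_quantile Spectral-edge power quantile.
#' @param onset_drop_bpm,onset_sustain_s Deceleration-onset criterion
#'   (drop below baseline in bpm, sustained duration in s).
#' @param peak_window_s Half-width of the deceleration-end SEF peak window, s.
#' @param abp_max_ext Seconds past occlusion end searched for ABP max.
#' @param spike_hz,floor_hz,persist,tol Onset-detector parameters.
#' @param abp_smooth_s Pulse-averaging window for the ABP series, s.
#' @param fhr_min_prominence Systolic-peak prominence threshold, mmHg.
#' @return A named list of class `uco_params`.
#' @export
uco_params <- function(window_s = 4, sef_quantile = 0.95,
                       onset_drop_bpm = 15, onset_sustain_s = 5,
                       peak_window_s = 20, abp_max_ext = 30,
                       spike_hz = 15, floor_hz = 6, persist = 3, tol = 0,
                       abp_smooth_s = 3, fhr_min_prominence = 5) {
  p <- as.list(environment())
  if (p$window_s <= 0 || p$sef_quantile <= 0 || p$sef_quantile > 1 ||
      p$persist < 1) {
    stop("uco_params: invalid parameter values")
  }
  structure(p, class = "uco_params")
}

#' Run the full analysis chain on one subject's recordings
#'
#' @param subject A `uco_subject` (or any list with `ecog`, `arterial`,
#'   `amniotic` traces, `events` and `samples`).
#' @param params A `uco_params` list.
#' @return A list: `baseline` (baseline means), `features` (per-event),
#'   `intervals` (10-min summaries), `onsets` (one-row onset result), the
#'   derived series (`fhr`, `abp`, `amp`, `sef`), and `samples`.
#' @export
analyze_subject <- function(subject, params = uco_params()) {
  abp_raw <- compute_abp(subject$arterial, subject$amniotic)
  abp <- smooth_abp(abp_raw, smooth_s = params$abp_smooth_s)
  fhr <- extract_fhr(abp_raw, min_prominence = params$fhr_min_prominence)
  ecog_p <- preprocess_ecog(subject$ecog)
  wf <- window_features(ecog_p, window_s = params$window_s,
                        sef_quantile = params$sef_quantile)
  events <- subject$events
  b_end <- if (!is.null(events) && nrow(events)) min(events$start_s) - 10 else
    trace_duration(subject$ecog)
  baseline <- baseline_summary(fhr, abp, wf$amp, wf$sef, c(0, b_end))
  features <- if (!is.null(events) && nrow(events)) {
    extract_all_features(events, fhr, abp, wf$amp, wf$sef, baseline,
                         onset_drop_bpm = params$onset_drop_bpm,
                         onset_sustain_s = params$onset_sustain_s,
                         peak_window_s = params$peak_window_s,
                         abp_max_ext = params$abp_max_ext)
  } else NULL
  intervals <- if (!is.null(features))
    interval_summaries(features, subject$samples) else NULL
  onsets <- detect_onsets(features, subject$samples,
                          spike_hz = params$spike_hz,
                          floor_hz = params$floor_hz,
                          persist = params$persist, tol = params$tol)
  onsets$subject_id <- subject$subject_id
  list(subject_id = subject$subject_id, baseline = baseline,
       features = features, intervals = intervals, onsets = onsets,
       fhr = fhr, abp = abp, amp = wf$amp, sef = wf$sef,
       samples = subject$samples, truth = subject$truth)
}

#' Simulate and analyse a whole cohort (the main study driver)
#'
#' Subjects are simulated and analysed one at a time (raw traces are
#' released after processing).  Pooled features, interval summaries and
#' onset results are aggregated into series summaries, the
#' repeated-measures comparisons of the per-series occlusion ECOG/
#' cardiovascular measures against baseline, and the pH correlations on
#' the pooled 10-min interval summaries.
#'
#' @param cfg A `uco_sim_config`.
#' @param params A `uco_params` list.
#' @param keep_series Keep per-subject derived series in the result
#'   (default `FALSE` to bound memory).
#' @return An object of class `uco_study`.
#' @export
cohort_study <- function(cfg, params = uco_params(), keep_series = FALSE) {
  stopifnot(inherits(cfg, "uco_sim_config"))
  set.seed(cfg$seed)
  traits <- draw_cohort_traits(cfg)
  subjects <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    su <- simulate_subject(cfg, traits[i, ])
    res <- analyze_subject(su, params)
    if (!keep_series) res[c("fhr", "abp", "amp", "sef")] <- NULL
    subjects[[i]] <- res
    rm(su); gc(FALSE)
  }
  build_study(cfg, params, traits, subjects)
}

#' Aggregate per-subject analysis results into a cohort study object
#' @noRd
build_study <- function(cfg, params, traits, subjects) {
  features <- do.call(rbind, lapply(subjects, `[[`, "features"))
  intervals <- do.call(rbind, lapply(subjects, `[[`, "intervals"))
  onsets <- do.call(rbind, lapply(subjects, `[[`, "onsets"))
  samples <- do.call(rbind, lapply(subjects, `[[`, "samples"))
  baseline_tbl <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, fhr = s$baseline$fhr,
               abp = s$baseline$abp, amp = s$baseline$amp,
               sef = s$baseline$sef, stringsAsFactors = FALSE)
  }))
  series_tbl <- if (!is.null(features)) series_summary(features) else NULL

  # subjects x (baseline, series...) tables for the repeated-measures tests
  measure_table <- function(col, baseline_col) {
    if (is.null(features)) return(NULL)
    series_levels <- intersect(c("mild", "moderate", "severe"),
                               unique(features$series))
    tab <- data.frame(baseline = baseline_tbl[[baseline_col]],
                      row.names = baseline_tbl$subject_id)
    for (se in series_levels) {
      f <- features[features$series == se, ]
      m <- tapply(f[[col]], f$subject_id, function(v) mean(v, na.rm = TRUE))
      tab[[se]] <- as.numeric(m[rownames(tab)])
    }
    tab
  }
  tables <- list(dec_amp = measure_table("dec_amp", "amp"),
                 dec_sef = measure_table("dec_sef", "sef"),
                 fhr_nadir = measure_table("fhr_nadir", "fhr"),
                 abp_max = measure_table("abp_max", "abp"))
  comparisons <- lapply(names(tables), function(nm) {
    if (is.null(tables[[nm]])) return(NULL)
    compare_to_baseline(tables[[nm]], measure = nm)
  })
  names(comparisons) <- names(tables)

  correlations <- NULL
  if (!is.null(intervals) && nrow(intervals) >= 4) {
    pairs <- list(c("dec_amp", "ph"), c("d_amp", "ph"), c("d_sef", "ph"),
                  c("abp_at_nadir", "ph"), c("d_abp_nadir", "ph"))
    correlations <- do.call(rbind, lapply(pairs, function(p) {
      tryCatch(correlate(intervals, p[1], p[2]), error = function(e) NULL)
    }))
  }

  structure(list(config = cfg, params = params, traits = traits,
                 subjects = subjects, features = features,
                 intervals = intervals, onsets = onsets, samples = samples,
                 baseline_tbl = baseline_tbl, series_tbl = series_tbl,
                 measure_tables = tables, comparisons = comparisons,
                 correlations = correlations),
            class = "uco_study")
}

#' @export
print.uco_study <- function(x, ...) {
  cat(sprintf("<uco_study> %d subjects, %d occlusions, %d detected spiking onsets\n",
              length(x$subjects),
              if (is.null(x$features)) 0L else nrow(x$features),
              sum(is.finite(x$onsets$spiking_onset_s))))
  invisible(x)
}

#' Run the whole pipeline and write all artifacts to a directory
#'
#' Stages: simulate, process, analyze-events, detect-onset, statistics,
#' report.  Writes pooled `events.csv`, `samples.csv`, `features.csv`,
#' `intervals.csv`, `onsets.csv`, the report tables, and a `manifest.json`
#' echoing the configuration, parameters and per-stage row counts.
#' Deterministic for a fixed `(config, seed)`.
#'
#' @param cfg A `uco_sim_config`.
#' @param out_dir Output directory.
#' @param params A `uco_params` list.
#' @return Invisibly, the `uco_study` object.
#' @export
run_pipeline <- function(cfg, out_dir, params = uco_params()) {
  study <- cohort_study(cfg, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
    nrow(df)
  }
  counts <- c(
    events = wr(do.call(rbind, lapply(study$subjects, function(s) {
      f <- s$features
      if (is.null(f)) NULL else f[, c("subject_id", "series", "start_s", "end_s")]
    })), "events.csv"),
    samples = wr(study$samples, "samples.csv"),
    features = wr(study$features, "features.csv"),
    intervals = wr(study$intervals, "intervals.csv"),
    onsets = wr(study$onsets, "onsets.csv")
  )
  render_report(study, out_dir)
  manifest <- list(
    package = "fetaluco",
    version = as.character(utils::packageVersion("fetaluco")),
    seed = cfg$seed, n_subjects = cfg$n_subjects,
    params = unclass(params),
    stages = c("simulate", "process", "analyze-events", "detect-onset",
               "statistics", "report"),
    rows = as.list(counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}
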