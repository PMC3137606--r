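# Subject- and cohort-level simulation drivers, plus on-disk writers.

#' Simulate one subject's complete recording session
#'
#' Draws (or receives) subject traits, builds the pH trajectory and blood
#' samples, the realised occlusion schedule, the spiking/hypotension onset
#' times (coupled draws in the pH domain), and synthesises the pressure and
#' ECOG channels.
#'
#' @param cfg A `uco_sim_config`.
#' @param traits Optional one-row traits data frame (from the cohort driver);
#'   drawn fresh under `seed` when `NULL`.
#' @param seed Seed used only when `traits` is `NULL`.
#' @return An object of class `uco_subject`: list with `subject_id`, traces
#'   (`ecog`, `arterial`, `amniotic`), `events`, `samples`, and `truth`
#'   (latent ground-truth values actually drawn).
#' @export
simulate_subject <- function(cfg, traits = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "uco_sim_config"))
  if (is.null(traits)) {
    set.seed(seed %||% cfg$seed)
    traits <- draw_single_traits(cfg)
  }
  set.seed(traits$seed)
  ph_curve <- simulate_ph(cfg, traits)
  events <- build_protocol(cfg, ph_curve)

  clip <- cfg$onset_ph_clip
  p0 <- min(max(cfg$spiking_onset_ph_mean + cfg$spiking_onset_ph_sd * traits$onset_z1,
                clip[1]), clip[2])
  rho <- cfg$onset_coupling
  zh <- rho * traits$onset_z1 + sqrt(1 - rho^2) * traits$onset_z2
  p0h <- min(max(cfg$spiking_onset_ph_mean - cfg$hypotension_onset_ph_lag +
                 cfg$spiking_onset_ph_sd * zh, clip[1] - 0.01), clip[2])
  onset_grid <- seq(ph_curve$layout$base_end, ph_curve$session_end, by = 0.5)
  tr_v <- ph_curve$trend(onset_grid)
  first_below <- function(p) {
    i <- match(TRUE, tr_v <= p)
    if (is.na(i)) NA_real_ else onset_grid[i]
  }
  spiking_onset_s <- if (nrow(events)) first_below(p0) else NA_real_
  hypotension_onset_s <- if (nrow(events)) first_below(p0h) else NA_real_

  truth <- list(
    subject_id = traits$subject_id,
    fhr_base = traits$fhr_base, fhr_nadir_mean = traits$fhr_nadir,
    abp_base = traits$abp_base,
    abp_peak = traits$abp_base + max(
      3, cfg$abp_uco_max_mean + 0.35 * (traits$abp_base - cfg$abp_baseline_mean) +
        traits$abp_peak_dev - traits$abp_base),
    c_amp = traits$c_amp, c_sef = traits$c_sef, burst_sef = traits$burst_sef,
    spiking_onset_ph = p0, hypotension_onset_ph = p0h,
    spiking_onset_s = spiking_onset_s,
    hypotension_onset_s = hypotension_onset_s,
    stop_s = ph_curve$stop_s, cross_s = ph_curve$cross_s,
    noise = TRUE
  )
  cardio <- simulate_cardio(cfg, events, ph_curve, truth)
  eres <- simulate_ecog(cfg, events, ph_curve, cardio$truth)

  ev <- events
  sm <- ph_curve$samples
  if (nrow(ev)) ev <- cbind(subject_id = traits$subject_id, ev)
  sm <- cbind(subject_id = traits$subject_id, sm)
  structure(list(subject_id = traits$subject_id,
                 ecog = eres$ecog, arterial = cardio$arterial,
                 amniotic = cardio$amniotic,
                 events = ev, samples = sm,
                 truth = eres$truth, ph_curve = ph_curve),
            class = "uco_subject")
}

#' @export
print.uco_subject <- function(x, ...) {
  cat(sprintf("<uco_subject %s> %.2f h, %d occlusions, %d samples, stop %s\n",
              x$subject_id, trace_duration(x$ecog) / 3600, nrow(x$events),
              nrow(x$samples),
              ifelse(is.na(x$truth$stop_s), "never",
                     sprintf("%.0f min", x$truth$stop_s / 60))))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Subject traits are drawn once at cohort level (stratified across the
#' cohort), then each subject is synthesised from its own child RNG stream.
#' Identical `(config, seed)` give bit-identical cohorts.
#'
#' @param cfg A `uco_sim_config`.
#' @return An object of class `uco_cohort`: list with `config`, `traits`,
#'   and `subjects` (list of `uco_subject`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "uco_sim_config"))
  set.seed(cfg$seed)
  traits <- draw_cohort_traits(cfg)
  subjects <- lapply(seq_len(nrow(traits)),
                     function(i) simulate_subject(cfg, traits[i, ]))
  structure(list(config = cfg, traits = traits, subjects = subjects),
            class = "uco_cohort")
}

#' @export
print.uco_cohort <- function(x, ...) {
  cat(sprintf("<uco_cohort> %d subjects (seed %s)\n", length(x$subjects),
              format(x$config$seed)))
  invisible(x)
}

#' Write a cohort's event logs, blood samples, truth and (optionally)
#' signal traces to a directory
#'
#' Events and samples are written as pooled CSVs; per-subject ground truth
#' as JSON.  Signal traces (large) are only written when `signals = TRUE`,
#' as per-subject `*_signal.csv` files with columns `time_s`, `value`,
#' optionally decimated by `signal_stride`.
#'
#' @param cohort A `uco_cohort`.
#' @param dir Output directory (created if needed).
#' @param signals Write raw traces as CSV (default `FALSE`).
#' @param signal_stride Keep every k-th sample when writing traces.
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir, signals = FALSE, signal_stride = 1L) {
  stopifnot(inherits(cohort, "uco_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- do.call(rbind, lapply(cohort$subjects, `[[`, "events"))
  sm <- do.call(rbind, lapply(cohort$subjects, `[[`, "samples"))
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(sm, file.path(dir, "samples.csv"), row.names = FALSE)
  for (su in cohort$subjects) {
    tr <- su$truth
    tr_out <- tr[setdiff(names(tr), "epochs")]
    tr_out$epochs <- su$truth$epochs
    jsonlite::write_json(tr_out,
                         file.path(dir, sprintf("%s_truth.json", su$subject_id)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (signals) {
      for (ch in c("ecog", "arterial", "amniotic")) {
        trc <- su[[ch]]
        idx <- seq(1L, length(trc$values), by = signal_stride)
        write.csv(data.frame(time_s = trace_times(trc)[idx],
                             value = trc$values[idx]),
                  file.path(dir, sprintf("%s_%s.csv", su$subject_id, ch)),
                  row.names = FALSE)
      }
    }
  }
  invisible(dir)
}
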