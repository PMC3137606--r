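# Realised occlusion schedule for one subject.

#' Build the occlusion event list from a configuration and a pH trajectory
#'
#' Fixed-duration series contribute their full schedule; the open-ended
#' (`until_ph`) series — and any series still running — is truncated at the
#' first measured blood sample with pH < 7.00 (the stop rule used during
#' the experiment: no occlusion starts after that sample).
#'
#' @param cfg A `uco_sim_config`.
#' @param ph_curve A `ph_curve` from [simulate_ph()].
#' @return A data frame of events: `series`, `start_s`, `end_s`, ordered and
#'   non-overlapping.  Empty (0-row) for an occlusion-free protocol.
#' @export
build_protocol <- function(cfg, ph_curve) {
  stopifnot(inherits(cfg, "uco_sim_config"), inherits(ph_curve, "ph_curve"))
  lay <- ph_curve$layout
  if (!length(lay$series)) {
    return(data.frame(series = character(0), start_s = numeric(0),
                      end_s = numeric(0), stringsAsFactors = FALSE))
  }
  has_open <- any(vapply(lay$series, function(se) se$open, logical(1)))
  if (has_open && is.na(ph_curve$stop_s)) {
    stop(sprintf(
      "build_protocol: pH never crossed 7.00 within %d min of severe occlusions (subject %s)",
      cfg$max_severe_min, ph_curve$traits$subject_id %||% "?"))
  }
  ev <- do.call(rbind, lapply(lay$series, function(se) {
    data.frame(series = se$name, start_s = se$starts,
               end_s = se$starts + se$occlusion_s, stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$start_s), , drop = FALSE]
  if (!is.na(ph_curve$stop_s)) ev <- ev[ev$start_s < ph_curve$stop_s, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
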