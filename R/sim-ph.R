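# Latent acidemia trajectory, blood-sampling schedule and measured samples.
#
# The pH trend is piecewise: flat baseline; shallow linear decline over the
# mild series; partial recovery in each 10-min occlusion-free gap; a convex
# (accelerating) decline over the moderate series; and a power-law decline
# over the severe series reaching 7.00 at the subject's latent crossing
# time.  Per-occlusion transient dips (ramp during the occlusion, exponential
# recovery after) are superimposed, so samples drawn at the end of the first
# occlusion of a series sit below the trend.  Occlusions stop at the first
# *measured* sample below 7.00 (the experiment's decision rule); pH then
# declines a little further over ~5 min before recovering.

#' Session layout from a configuration
#'
#' Computes series start times and nominal occlusion-start grids.  The
#' severe (`until_ph`) series grid extends to `max_severe_min`; the realised
#' series is truncated at the measured pH crossing by [build_protocol()].
#' @noRd
session_layout <- function(cfg) {
  base_end <- cfg$baseline_minutes * 60
  t <- base_end
  series <- list()
  p <- cfg$protocol
  for (k in seq_len(nrow(p))) {
    row <- p[k, ]
    if (row$duration_policy == "fixed_1h") {
      n_ev <- floor(3600 / row$period_s)
      starts <- t + (seq_len(n_ev) - 1L) * row$period_s
      series[[row$series]] <- list(name = row$series, start = t, end = t + 3600,
                                   starts = starts, occlusion_s = row$occlusion_s,
                                   period_s = row$period_s, open = FALSE)
      t <- t + 3600 + cfg$gap_s
    } else if (row$duration_policy == "until_ph") {
      n_max <- ceiling(cfg$max_severe_min * 60 / row$period_s)
      starts <- t + (seq_len(n_max) - 1L) * row$period_s
      series[[row$series]] <- list(name = row$series, start = t, end = NA,
                                   starts = starts, occlusion_s = row$occlusion_s,
                                   period_s = row$period_s, open = TRUE)
      t <- t + cfg$max_severe_min * 60
    } else stop("unknown duration_policy: ", row$duration_policy)
  }
  list(base_end = base_end, series = series, cap_end = t)
}

#' Snap a nominal sample time to the midpoint of an inter-occlusion gap
#' @noRd
snap_to_gap <- function(t_nominal, starts, occlusion_s, period_s) {
  if (!length(starts)) return(t_nominal)
  k <- findInterval(t_nominal, starts)
  if (k < 1L) k <- 1L
  starts[k] + occlusion_s + (period_s - occlusion_s) / 2
}

#' Blood-gas values consistent with a sample's pH and occlusion context
#' @noRd
gas_values <- function(ph, during_occlusion) {
  acid_co2 <- smoothstep((7.10 - ph) / 0.20)
  acid_o2 <- smoothstep((7.25 - ph) / 0.30)
  if (during_occlusion) {
    c(pO2 = 10.4 + rnorm(1, 0, 1), pCO2 = 57.5 + rnorm(1, 0, 1.5),
      O2Sat = max(2, 17.5 + rnorm(1, 0, 2.5)))
  } else {
    c(pO2 = 18.5 + rnorm(1, 0, 0.8),
      pCO2 = 53 + 24 * acid_co2 + rnorm(1, 0, 1.2),
      O2Sat = max(5, 47 - 20 * acid_o2 + rnorm(1, 0, 3)))
  }
}

#' Simulate the pH trajectory and arterial blood samples for one subject
#'
#' @param cfg A `uco_sim_config`.
#' @param traits One-row data frame of subject traits (see
#'   `draw_cohort_traits`); drawn fresh when `NULL`.
#' @return An object of class `ph_curve`: a list with the trend function
#'   `trend(t)` (latent, occlusion dips excluded), the full curve `ph(t)`
#'   (trend + dips), the measured `samples` data frame (`time_s`, `phase`,
#'   `pH`, `pO2_mmHg`, `pCO2_mmHg`, `O2Sat_pct`), the measured stop time
#'   `stop_s` (first sample below pH 7.00; `NA` when never crossed), the
#'   latent crossing time `cross_s`, and `session_end`.
#' @export
simulate_ph <- function(cfg, traits = NULL) {
  stopifnot(inherits(cfg, "uco_sim_config"))
  if (is.null(traits)) traits <- draw_single_traits(cfg)
  lay <- session_layout(cfg)
  s <- traits$severity
  ph0 <- traits$ph_base
  rec <- cfg$gap_recovery

  mild <- lay$series[["mild"]]; mod <- lay$series[["moderate"]]
  sev <- lay$series[["severe"]]
  v_mild_end <- ph0 - (if (!is.null(mild)) cfg$mild_drop * s else 0)
  v_mod_start <- v_mild_end + (if (!is.null(mild) && !is.null(mod)) rec[1] else 0)
  mod_cross_target <- 6.972 + rnorm(1, 0, 0.008)
  d_mod <- if (is.null(mod)) 0 else if (isTRUE(traits$moderate_cross)) {
    v_mod_start - mod_cross_target
  } else cfg$moderate_drop * s
  v_mod_end <- v_mod_start - d_mod
  v_sev_start <- v_mod_end + (if (!is.null(mod) && !is.null(sev)) rec[2] else 0)
  t_sev_cross <- traits$t_severe_min * 60

  core_trend <- function(t) {
    v <- rep(ph0, length(t))
    if (!is.null(mild)) {
      i <- t >= mild$start & t < mild$end
      v[i] <- ph0 - cfg$mild_drop * s * (t[i] - mild$start) / 3600
      i <- t >= mild$end
      v[i] <- v_mild_end
    }
    if (!is.null(mod)) {
      g0 <- mild$end %||% lay$base_end
      i <- t >= g0 & t < mod$start
      v[i] <- v_mild_end + rec[1] * (t[i] - g0) / (mod$start - g0)
      i <- t >= mod$start & t < mod$end
      v[i] <- v_mod_start - d_mod * ((t[i] - mod$start) / 3600)^cfg$moderate_shape
      i <- t >= mod$end
      v[i] <- v_mod_end
    }
    if (!is.null(sev)) {
      g0 <- mod$end %||% lay$base_end
      i <- t >= g0 & t < sev$start
      v[i] <- v_mod_end + rec[2] * (t[i] - g0) / (sev$start - g0)
      i <- t >= sev$start
      v[i] <- v_sev_start - (v_sev_start - 7.00) *
        ((t[i] - sev$start) / t_sev_cross)^cfg$severe_shape
    }
    v
  }

  # per-occlusion transient dips (all series, nominal grids)
  dip_events <- do.call(rbind, lapply(lay$series, function(se) {
    amp <- unname(cfg$dip_amp[se$name])
    if (is.na(amp)) amp <- 0
    data.frame(start = se$starts, occ = se$occlusion_s, amp = amp * s)
  }))
  dips <- function(t) {
    d <- numeric(length(t))
    if (is.null(dip_events) || nrow(dip_events) == 0L) return(d)
    for (k in seq_len(nrow(dip_events))) {
      st <- dip_events$start[k]; en <- st + dip_events$occ[k]
      a <- dip_events$amp[k]
      i <- t >= st & t < en
      d[i] <- d[i] + a * (t[i] - st) / (en - st)
      j <- t >= en & t < en + 8 * cfg$dip_tau_s
      d[j] <- d[j] + a * exp(-(t[j] - en) / cfg$dip_tau_s)
    }
    d
  }

  # ---- sampling schedule ----
  sched <- data.frame(time = numeric(0), phase = character(0),
                      occl = logical(0), stringsAsFactors = FALSE)
  add <- function(time, phase, occl = FALSE) {
    sched <<- rbind(sched, data.frame(time = time, phase = phase, occl = occl,
                                      stringsAsFactors = FALSE))
  }
  if (lay$base_end >= 600) add(max(lay$base_end - 1800, lay$base_end / 2), "baseline")
  for (se in lay$series) {
    add(se$starts[1] + se$occlusion_s, paste0(se$name, "_uco1"), occl = TRUE)
    if (!se$open) {
      add(max(se$starts) + se$occlusion_s + 300, paste0("post_", se$name))
    }
    if (se$name %in% c("moderate", "severe")) {
      marks <- seq(1200, (if (se$open) cfg$max_severe_min * 60 else 3500), by = 1200)
      for (m in marks) {
        add(snap_to_gap(se$start + m, se$starts, se$occlusion_s, se$period_s),
            paste0(se$name, "_", round(m / 60), "min"))
      }
    }
  }
  sched <- sched[order(sched$time), , drop = FALSE]

  # ---- measure in time order, applying the stop rule ----
  stop_s <- NA_real_
  meas <- numeric(nrow(sched))
  for (k in seq_len(nrow(sched))) {
    tk <- sched$time[k]
    meas[k] <- core_trend(tk) - dips(tk) + rnorm(1, 0, cfg$ph_sample_noise_sd)
    if (is.na(stop_s) && meas[k] < 7.00 && tk > lay$base_end) {
      stop_s <- tk
      keep <- seq_len(k)
      sched <- sched[keep, , drop = FALSE]
      meas <- meas[keep]
      break
    }
  }

  r_end <- if (!is.na(stop_s)) {
    max(0, (core_trend(stop_s - 30) - core_trend(stop_s + 30)) / 60)
  } else 0
  trend <- function(t) {
    v <- core_trend(t)
    if (!is.na(stop_s)) {
      i <- t > stop_s & t <= stop_s + 300
      v[i] <- core_trend(stop_s) - 0.5 * r_end * (t[i] - stop_s)
      j <- t > stop_s + 300
      v_p <- core_trend(stop_s) - 150 * r_end
      v[j] <- v_p + (cfg$ph_recovery_target - v_p) *
        (1 - exp(-(t[j] - stop_s - 300) / 1800))
    }
    v
  }
  if (!is.na(stop_s)) {
    tp <- stop_s + 300
    meas <- c(meas, trend(tp) - dips(tp) + rnorm(1, 0, cfg$ph_sample_noise_sd))
    sched <- rbind(sched, data.frame(time = tp, phase = "post_stop", occl = FALSE,
                                     stringsAsFactors = FALSE))
  }
  gases <- t(vapply(seq_len(nrow(sched)),
                    function(k) gas_values(meas[k], sched$occl[k]), numeric(3)))
  samples <- data.frame(time_s = sched$time, phase = sched$phase,
                        pH = meas, pO2_mmHg = gases[, 1], pCO2_mmHg = gases[, 2],
                        O2Sat_pct = gases[, 3], stringsAsFactors = FALSE)

  session_end <- if (!is.na(stop_s)) stop_s + cfg$post_stop_s else lay$cap_end
  grid <- seq(0, session_end, by = 1)
  tv <- trend(grid) - dips(grid)
  cross_s <- if (any(tv < 7.00)) grid[match(TRUE, tv < 7.00)] else NA_real_

  structure(list(trend = trend,
                 ph = function(t) trend(t) - dips(t),
                 dips = dips, samples = samples, stop_s = stop_s,
                 cross_s = cross_s, session_end = session_end,
                 layout = lay, traits = traits),
            class = "ph_curve")
}

#' @export
print.ph_curve <- function(x, ...) {
  cat(sprintf("<ph_curve> baseline %.2f, stop %s, %d samples\n",
              x$trend(0), ifelse(is.na(x$stop_s), "never",
                                 sprintf("%.0fs", x$stop_s)),
              nrow(x$samples)))
  invisible(x)
}
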