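# Core containers: uniformly sampled signal traces and derived series.

#' Construct a uniformly sampled signal trace
#'
#' A `signal_trace` holds one channel of a continuous recording: sample
#' values, sampling rate, start time and physical units.
#'
#' @param values Numeric vector of samples; must be finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#' @param units Unit string, e.g. `"uV"` or `"mmHg"`.
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), fs = 1000, units = "uV")
#' trace_duration(tr)
#' @export
signal_trace <- function(values, fs, t0 = 0, units = "") {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!all(is.finite(values))) stop("signal_trace: values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("signal_trace: fs must be a positive scalar")
  }
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 t0 = as.numeric(t0), units = as.character(units)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz, t0 = %gs, %.1fs, units = %s\n",
              length(x$values), x$fs, x$t0, trace_duration(x), x$units))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace A `signal_trace`.
#' @return Duration in seconds (`length / fs`).
#' @export
trace_duration <- function(trace) length(trace$values) / trace$fs

#' Sample times of a trace
#' @param trace A `signal_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) trace$t0 + (seq_along(trace$values) - 1L) / trace$fs

#' Extract a time slice of a trace as a plain numeric vector
#' @noRd
trace_slice <- function(trace, from, to) {
  i0 <- max(1L, ceiling((from - trace$t0) * trace$fs) + 1L)
  i1 <- min(length(trace$values), floor((to - trace$t0) * trace$fs) + 1L)
  if (i1 < i0) return(numeric(0))
  trace$values[i0:i1]
}

#' Construct a derived series (irregular or windowed time series)
#'
#' Derived series carry the pipeline's reduced signals: 4-s ECOG amplitude
#' (`AMP_uV`) and spectral edge (`SEF95_Hz`) window series, beat-time heart
#' rate (`FHR_bpm`) and pulse-averaged blood pressure (`ABP_mmHg`).
#'
#' @param times Strictly increasing times in seconds (window centers or beat
#'   times).
#' @param values Numeric values, same length as `times`.
#' @param kind One of `"AMP_uV"`, `"SEF95_Hz"`, `"FHR_bpm"`, `"ABP_mmHg"`.
#' @param flags Optional logical vector marking interpolated/suspect points.
#' @return An object of class `derived_series`.
#' @export
derived_series <- function(times, values, kind, flags = NULL) {
  kind <- match.arg(kind, c("AMP_uV", "SEF95_Hz", "FHR_bpm", "ABP_mmHg"))
  stopifnot(length(times) == length(values))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("derived_series: times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind,
                 flags = if (is.null(flags)) logical(length(times)) else flags),
            class = "derived_series")
}

#' @export
print.derived_series <- function(x, ...) {
  cat(sprintf("<derived_series:%s> %d points%s\n", x$kind, length(x$times),
              if (length(x$times)) sprintf(" over [%.1f, %.1f]s", x$times[1],
                                           x$times[length(x$times)]) else ""))
  invisible(x)
}

#' Values of a derived series within a half-open time window [from, to)
#' @param series A `derived_series`.
#' @param from,to Window bounds in seconds.
#' @return Numeric vector of values whose times fall in the window.
#' @export
series_window <- function(series, from, to) {
  series$values[series$times >= from & series$times < to]
}

#' Convert a derived series to a data frame
#' @param x A `derived_series`.
#' @param ... Unused.
#' @return A data frame with columns `time_s`, `value`, `kind`, `flag`.
#' @export
as.data.frame.derived_series <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, kind = x$kind, flag = x$flags)
}
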