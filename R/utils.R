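# Internal numerical helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Child RNG seed for a subject, fixed-offset scheme so cohorts are
#' reproducible when the subject count changes.
#' @noRd
child_seed <- function(master_seed, index) {
  s <- (as.numeric(master_seed) + 10007 * as.numeric(index)) %% 2147483647
  as.integer(max(1, s))
}

#' Stratified normal draws: permuted mid-quantiles mapped through qnorm.
#' Keeps the sample mean at `mean` (symmetric quantiles) while the spread
#' stays close to `sd`; used for between-subject trait draws so a small
#' virtual cohort is representative of its population.
#' @noRd
stratified_normal <- function(n, mean, sd) {
  if (n == 1L) return(rnorm(1L, mean, sd))
  p <- (seq_len(n) - 0.5) / n
  qnorm(sample(p), mean = mean, sd = sd)
}

#' Stratified lognormal draws (quantile-stratified on the log scale).
#' @noRd
stratified_lognormal <- function(n, meanlog, sdlog, lo = -Inf, hi = Inf) {
  x <- exp(stratified_normal(n, meanlog, sdlog))
  pmin(pmax(x, lo), hi)
}

#' Ornstein-Uhlenbeck noise (AR(1) discretisation) with stationary sd `sd`
#' and correlation time `tau` seconds, sampled at `fs` Hz.
#' @noRd
ou_noise <- function(n, fs, tau, sd) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  innov_sd <- sd * sqrt(1 - a^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), a, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

#' Centered moving average via cumulative sums; edges use shrunken windows.
#' @noRd
rolling_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  if (k >= n) return(rep(mean(x), n))
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Smoothstep ramp from 0 to 1 on [0, 1], clamped outside.
#' @noRd
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Standard error of the mean; NA-safe, 0 (with attribute) for n = 1.
#' @noRd
sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n <= 1L) return(0)
  sd(x) / sqrt(n)
}
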