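# Repeated-measures comparisons against baseline, correlations on the
# 10-min interval summaries, and report rendering.
#
# Following the original analysis scheme: per-condition normality is
# assessed with a Kolmogorov-Smirnov test (Lilliefors form, moments
# estimated); normal measures go through one-way repeated-measures ANOVA
# with Bonferroni-corrected paired post-hocs vs baseline, non-normal
# measures through the Friedman rank test with Wilcoxon signed-rank
# post-hocs vs baseline under step-down (Holm) correction.  Overall test
# p-values can alternatively be computed by within-subject label
# permutation.

#' Lilliefors-type normality check; non-normal on failure or tiny n
#' @noRd
is_normalish <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5L || sd(x) == 0) return(FALSE)
  p <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Friedman chi-square statistic (average ranks within subjects)
#' @noRd
friedman_statistic <- function(mat) {
  r <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  cs <- colSums(r)
  num <- 12 * sum((cs - n * (k + 1) / 2)^2)
  # tie correction as in the classical definition
  ties <- apply(mat, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (den <= 0) return(0)
  num / den
}

#' Repeated-measures F statistic for a subjects x conditions table
#' @noRd
rm_anova_statistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1; df_err <- (k - 1) * (n - 1)
  if (ss_err <= 0) return(Inf)
  (ss_cond / df_cond) / (ss_err / df_err)
}

#' Permutation test for repeated-measures tables
#'
#' Permutes condition labels independently within each subject and compares
#' the observed Friedman chi-square or repeated-measures F statistic with
#' its permutation distribution.
#'
#' @param tbl Numeric matrix or data frame, subjects x conditions, complete
#'   cases only.
#' @param stat `"friedman"` or `"rm_anova"`.
#' @param n_perm Number of permutations (default 10000).
#' @return A list with `statistic` and `p_value`
#'   (`(1 + #{perm >= obs}) / (n_perm + 1)`).
#' @export
perm_test_repeated <- function(tbl, stat = c("friedman", "rm_anova"),
                               n_perm = 10000) {
  stat <- match.arg(stat)
  mat <- as.matrix(tbl)
  f <- if (stat == "friedman") friedman_statistic else rm_anova_statistic
  obs <- f(mat)
  k <- ncol(mat)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pm <- t(apply(mat, 1, function(row) row[sample.int(k)]))
    if (f(pm) >= obs - 1e-12) count <- count + 1L
  }
  list(statistic = obs, p_value = (1 + count) / (n_perm + 1))
}

#' Compare conditions to baseline for one measure
#'
#' @param tbl Data frame or matrix, rows = subjects, columns = conditions;
#'   the first (or `baseline_col`) column is the baseline.  Subjects with
#'   any missing cell are excluded listwise.
#' @param measure Label carried into the result.
#' @param baseline_col Index or name of the baseline column.
#' @param alpha Significance level (default 0.05).
#' @param p_method `"asymptotic"` (RM-ANOVA / Friedman as implemented in
#'   stats) or `"permutation"` (within-subject label permutation).
#' @param n_perm Permutations for `p_method = "permutation"`.
#' @return A data frame of `ComparisonResult` rows: one `(overall)` row for
#'   the omnibus test plus one row per non-baseline condition with its
#'   mean, SEM, post-hoc statistic, adjusted p-value and significance flag.
#'   With fewer than 3 complete subjects the result is flagged
#'   `underpowered` and carries no p-values.
#' @export
compare_to_baseline <- function(tbl, measure = "", baseline_col = 1,
                                alpha = 0.05,
                                p_method = c("asymptotic", "permutation"),
                                n_perm = 10000) {
  p_method <- match.arg(p_method)
  mat <- as.matrix(as.data.frame(tbl))
  if (is.character(baseline_col)) baseline_col <- match(baseline_col, colnames(mat))
  mat <- mat[, c(baseline_col, setdiff(seq_len(ncol(mat)), baseline_col)),
             drop = FALSE]
  cc <- complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  conds <- colnames(mat) %||% paste0("cond", seq_len(ncol(mat)))
  n <- nrow(mat); k <- ncol(mat)

  base_row <- function(cond, i) data.frame(
    measure = measure, condition = cond, n = n,
    mean = mean(mat[, i]), sem = sem(mat[, i]),
    test = NA_character_, statistic = NA_real_, p_value = NA_real_,
    significant_vs_baseline = FALSE, underpowered = n < 3,
    stringsAsFactors = FALSE)

  if (n < 3) {
    out <- do.call(rbind, lapply(seq_len(k), function(i) base_row(conds[i], i)))
    return(out)
  }

  normal <- all(vapply(seq_len(k), function(i) is_normalish(mat[, i]), logical(1)))
  long <- data.frame(y = as.vector(mat),
                     condition = factor(rep(conds, each = n), levels = conds),
                     subject = factor(rep(seq_len(n), k)))
  if (normal) {
    test_name <- "RM-ANOVA"
    if (p_method == "permutation") {
      pr <- perm_test_repeated(mat, "rm_anova", n_perm)
      statistic <- pr$statistic; p_overall <- pr$p_value
    } else {
      fit <- aov(y ~ condition + Error(subject), data = long)
      s <- summary(fit)[["Error: Within"]][[1]]
      statistic <- s[["F value"]][1]; p_overall <- s[["Pr(>F)"]][1]
    }
    ph <- vapply(2:k, function(i) {
      tt <- t.test(mat[, i], mat[, 1], paired = TRUE)
      c(tt$statistic, tt$p.value)
    }, numeric(2))
    p_adj <- p.adjust(ph[2, ], method = "bonferroni")
  } else {
    test_name <- "Friedman"
    if (p_method == "permutation") {
      pr <- perm_test_repeated(mat, "friedman", n_perm)
      statistic <- pr$statistic; p_overall <- pr$p_value
    } else {
      ft <- tryCatch(friedman.test(mat), error = function(e) NULL)
      statistic <- if (is.null(ft) || !is.finite(ft$statistic)) 0 else
        unname(ft$statistic)
      p_overall <- if (is.null(ft) || !is.finite(ft$p.value)) 1 else ft$p.value
    }
    ph <- vapply(2:k, function(i) {
      if (all(mat[, i] == mat[, 1])) return(c(0, 1))
      wt <- suppressWarnings(wilcox.test(mat[, i], mat[, 1], paired = TRUE,
                                         exact = FALSE))
      c(unname(wt$statistic), wt$p.value)
    }, numeric(2))
    p_adj <- p.adjust(ph[2, ], method = "holm")
  }

  rows <- list()
  overall <- base_row("(overall)", 1)
  overall$mean <- NA_real_; overall$sem <- NA_real_
  overall$test <- test_name; overall$statistic <- statistic
  overall$p_value <- p_overall
  rows[[1]] <- overall
  rows[[2]] <- base_row(conds[1], 1)
  for (i in 2:k) {
    r <- base_row(conds[i], i)
    r$test <- if (normal) "paired t (Bonferroni)" else "Wilcoxon signed-rank (Holm)"
    r$statistic <- ph[1, i - 1]
    r$p_value <- p_adj[i - 1]
    r$significant_vs_baseline <- is.finite(p_overall) && p_overall < alpha &&
      is.finite(p_adj[i - 1]) && p_adj[i - 1] < alpha
    rows[[i + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between two interval-summary fields
#'
#' @param intervals Data frame of pooled interval summaries.
#' @param x,y Column names.
#' @param method `"auto"` (Pearson when both margins pass the normality
#'   check, Spearman otherwise), `"pearson"` or `"spearman"`.
#' @return A one-row data frame (`CorrelationResult`): `x`, `y`, `n`,
#'   `method`, `R`, `p_value`, `degenerate` (zero variance in a margin).
#' @export
correlate <- function(intervals, x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  xv <- intervals[[x]]; yv <- intervals[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 4L) stop("correlate: need at least 4 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(data.frame(x = x, y = y, n = n, method = method, R = NA_real_,
                      p_value = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  if (method == "auto") {
    method <- if (is_normalish(xv) && is_normalish(yv)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  data.frame(x = x, y = y, n = n, method = method, R = unname(ct$estimate),
             p_value = ct$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Render cohort-study results as CSV tables and a markdown report
#'
#' Writes `table1.csv` (blood gases / pH by sampling phase), `table2.csv`
#' (cardiovascular), `table3.csv` (ECOG), `onsets.csv`,
#' `correlations.csv` and `report.md` into `dir`.  Rendering is
#' deterministic: identical inputs give byte-identical files.  Missing
#' upstream pieces produce header-only tables rather than errors.
#'
#' @param study A `uco_study` from [cohort_study()] (or a compatible list).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m, s) ifelse(is.na(m), "", sprintf("%.3g ± %.2g", m, s))
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  # Table 1: samples by phase
  smp <- study$samples
  if (!is.null(smp) && nrow(smp)) {
    agg <- do.call(rbind, lapply(split(smp, smp$phase), function(g) {
      data.frame(phase = g$phase[1], n = nrow(g),
                 pH = fmt(mean(g$pH), sem(g$pH)),
                 pO2_mmHg = fmt(mean(g$pO2_mmHg), sem(g$pO2_mmHg)),
                 pCO2_mmHg = fmt(mean(g$pCO2_mmHg), sem(g$pCO2_mmHg)),
                 O2Sat_pct = fmt(mean(g$O2Sat_pct), sem(g$O2Sat_pct)),
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(vapply(split(smp, smp$phase), function(g) min(g$time_s),
                            numeric(1))), , drop = FALSE]
  } else {
    agg <- data.frame(phase = character(0), n = integer(0), pH = character(0),
                      pO2_mmHg = character(0), pCO2_mmHg = character(0),
                      O2Sat_pct = character(0))
  }
  wr(agg, "table1.csv")

  # Table 2: cardiovascular
  bt <- study$baseline_tbl
  st <- study$series_tbl
  t2 <- data.frame(row = "Baseline",
                   mean_FHR_bpm = if (!is.null(bt)) fmt(mean(bt$fhr), sem(bt$fhr)) else "",
                   mean_ABP_mmHg = if (!is.null(bt)) fmt(mean(bt$abp), sem(bt$abp)) else "",
                   FHR_nadir_bpm = "", ABP_max_mmHg = "", ABP_at_FHR_nadir_mmHg = "",
                   stringsAsFactors = FALSE)
  if (!is.null(st)) {
    for (se in unique(st$series)) {
      g <- function(m) {
        r <- st[st$series == se & st$measure == m, ]
        if (nrow(r)) fmt(r$mean, r$sem) else ""
      }
      t2 <- rbind(t2, data.frame(row = paste(se, "UCO series"),
                                 mean_FHR_bpm = "", mean_ABP_mmHg = "",
                                 FHR_nadir_bpm = g("fhr_nadir"),
                                 ABP_max_mmHg = g("abp_max"),
                                 ABP_at_FHR_nadir_mmHg = g("abp_at_nadir"),
                                 stringsAsFactors = FALSE))
    }
  }
  wr(t2, "table2.csv")

  # Table 3: ECOG
  sig_mark <- function(measure, cond) {
    cmp <- study$comparisons[[measure]]
    if (is.null(cmp)) return("")
    r <- cmp[cmp$condition == cond, ]
    if (nrow(r) && isTRUE(r$significant_vs_baseline[1])) "*" else ""
  }
  t3 <- data.frame(row = "Baseline",
                   mean_AMP_uV = if (!is.null(bt)) fmt(mean(bt$amp), sem(bt$amp)) else "",
                   mean_SEF_Hz = if (!is.null(bt)) fmt(mean(bt$sef), sem(bt$sef)) else "",
                   UCO_AMP_uV = "", UCO_SEF_Hz = "", UCO_dAMP_uV = "",
                   UCO_dSEF_Hz = "", stringsAsFactors = FALSE)
  if (!is.null(st)) {
    for (se in unique(st$series)) {
      g <- function(m, mark = "") {
        r <- st[st$series == se & st$measure == m, ]
        if (nrow(r)) paste0(fmt(r$mean, r$sem), mark) else ""
      }
      t3 <- rbind(t3, data.frame(
        row = paste(se, "UCO series"),
        mean_AMP_uV = g("pre30_amp"), mean_SEF_Hz = g("pre30_sef"),
        UCO_AMP_uV = g("dec_amp", sig_mark("dec_amp", se)),
        UCO_SEF_Hz = g("dec_sef", sig_mark("dec_sef", se)),
        UCO_dAMP_uV = g("d_amp"), UCO_dSEF_Hz = g("d_sef"),
        stringsAsFactors = FALSE))
    }
  }
  wr(t3, "table3.csv")

  wr(study$onsets %||% data.frame(), "onsets.csv")
  wr(study$correlations %||% data.frame(), "correlations.csv")

  md <- c("# UCO cohort analysis report", "",
          sprintf("Subjects: %d", length(study$subjects %||% list())),
          sprintf("Seed: %s", format(study$config$seed %||% NA)), "",
          "## Parameters", "",
          paste0("- ", names(study$params %||% list()), " = ",
                 vapply(study$params %||% list(), function(p)
                   paste(format(p), collapse = ","), character(1))),
          "", "## Outputs", "",
          paste0("- ", basename(paths)))
  writeLines(md, file.path(dir, "report.md"))
  invisible(c(paths, file.path(dir, "report.md")))
}
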