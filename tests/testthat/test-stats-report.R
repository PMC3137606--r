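# Repeated-measures statistics, correlations, and report rendering.

test_that("identical conditions give a null Friedman result, no flags", {
  tbl <- matrix(5, nrow = 6, ncol = 4,
                dimnames = list(NULL, c("baseline", "a", "b", "c")))
  res <- compare_to_baseline(tbl, measure = "const")
  ov <- res[res$condition == "(overall)", ]
  expect_equal(ov$test, "Friedman")                 # zero variance: rank path
  expect_equal(ov$statistic, 0)
  expect_false(any(res$significant_vs_baseline))
})

test_that("a strongly shifted condition is flagged significant, others not", {
  set.seed(601)
  n <- 8
  base <- rnorm(n)
  tbl <- data.frame(baseline = base, a = base + rnorm(n, 0, 1),
                    b = base + 10 + rnorm(n, 0, 1), c = base + rnorm(n, 0, 1))
  res <- compare_to_baseline(tbl, measure = "shifted")
  expect_true(res$significant_vs_baseline[res$condition == "b"])
  expect_false(res$significant_vs_baseline[res$condition == "a"])
  expect_false(res$significant_vs_baseline[res$condition == "c"])
  ov <- res[res$condition == "(overall)", ]
  expect_lt(ov$p_value, 0.05)
  # the permutation route agrees with an independent permutation oracle
  mat <- as.matrix(tbl)
  set.seed(602)
  pk <- compare_to_baseline(tbl, p_method = "permutation", n_perm = 2000)
  p_pkg <- pk$p_value[pk$condition == "(overall)"]
  set.seed(603)
  p_ora <- oracle_perm_p(mat, oracle_rm_F, 2000)
  mc <- 3 * sqrt(0.05 * 0.95 / 2000) + 0.005
  expect_lt(abs(p_pkg - p_ora), max(mc, 0.02))
})

test_that("underpowered tables carry no p-values", {
  tbl <- matrix(rnorm(8), nrow = 2, ncol = 4,
                dimnames = list(NULL, c("baseline", "a", "b", "c")))
  res <- compare_to_baseline(tbl)
  expect_true(all(res$underpowered))
  expect_true(all(is.na(res$p_value)))
})

test_that("permutation p-values match brute-force oracles on 6x4 tables", {
  set.seed(604)
  for (case in 1:3) {
    mat <- matrix(rnorm(24, sd = 1), nrow = 6, ncol = 4)
    mat[, 2] <- mat[, 2] + case - 1        # effect size 0, 1, 2 SD
    set.seed(604 + case)
    pf <- perm_test_repeated(mat, "friedman", n_perm = 3000)
    set.seed(700 + case)
    po <- oracle_perm_p(mat, oracle_friedman, 3000)
    tol_f <- 3 * sqrt(max(pf$p_value, 0.01) * 0.99 / 3000) + 0.01
    expect_lt(abs(pf$p_value - po), max(tol_f, 0.025))

    set.seed(804 + case)
    pa <- perm_test_repeated(mat, "rm_anova", n_perm = 3000)
    set.seed(900 + case)
    pao <- oracle_perm_p(mat, oracle_rm_F, 3000)
    tol_a <- 3 * sqrt(max(pa$p_value, 0.01) * 0.99 / 3000) + 0.01
    expect_lt(abs(pa$p_value - pao), max(tol_a, 0.025))
  }
})

test_that("correlations pick the right method and respect degeneracy", {
  x <- seq(0.1, 2, length.out = 40)
  df <- data.frame(x = x, y_lin = 2 * x + 1, y_exp = exp(3 * x),
                   z = rep(1, 40))
  r1 <- correlate(df, "x", "y_lin", method = "pearson")
  expect_equal(r1$R, 1, tolerance = 1e-12)
  r2 <- correlate(df, "x", "y_exp", method = "auto")
  expect_equal(r2$method, "spearman")               # skewed margin
  expect_equal(r2$R, 1, tolerance = 1e-12)
  r3 <- correlate(df, "x", "z")
  expect_true(r3$degenerate); expect_true(is.na(r3$R))
  expect_error(correlate(df[1:3, ], "x", "y_lin"), "4 complete pairs")
  # sign invariance under positive affine rescaling
  set.seed(605)
  df2 <- data.frame(a = rnorm(30))
  df2$b <- -0.7 * df2$a + rnorm(30, 0, 0.5)
  df2$b_scaled <- 100 * df2$b + 5
  expect_equal(sign(correlate(df2, "a", "b", method = "pearson")$R),
               sign(correlate(df2, "a", "b_scaled", method = "pearson")$R))
})

test_that("interval correlations on the cohort carry the expected signs", {
  st <- default_study()
  co <- st$correlations
  g <- function(xn) co$R[co$x == xn]
  expect_gt(g("dec_amp"), 0)        # occlusion ECOG amplitude falls with pH
  expect_lt(g("d_amp"), 0)          # prior-minus-during AMP grows as pH falls
  expect_lt(g("d_sef"), 0)          # prior-minus-during SEF grows as pH falls
  expect_gt(g("abp_at_nadir"), 0)   # nadir pressure falls with pH
  expect_gt(g("d_abp_nadir"), 0)    # its baseline-relative change falls too
})

test_that("report rendering is structural, complete and deterministic", {
  st <- default_study()
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  render_report(st, d1)
  render_report(st, d2)
  files <- c("table1.csv", "table2.csv", "table3.csv", "onsets.csv",
             "correlations.csv", "report.md")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  t2 <- read.csv(file.path(d1, "table2.csv"))
  expect_true(all(c("Baseline", "mild UCO series", "moderate UCO series",
                    "severe UCO series") %in% t2$row))
  # empty study: header-only tables, no error
  d0 <- file.path(tempdir(), "rep0")
  render_report(list(), d0)
  expect_true(all(file.exists(file.path(d0, files))))
  expect_equal(nrow(read.csv(file.path(d0, "table1.csv"))), 0)
})
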