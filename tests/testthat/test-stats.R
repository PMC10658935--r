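make_manifest <- function(n, strata = 1L) {
  data.frame(case_id = sprintf("c%03d", seq_len(n)),
             pathology = rep(c("malignant", "benign"), length.out = strata)[
               rep(seq_len(strata), length.out = n)],
             enhancement_type = "mass",
             size_bin = rep(c("<5", "5 to 9", "10 to 14", "15 to 19", ">20"),
                            length.out = strata)[rep(seq_len(strata), length.out = n)],
             stringsAsFactors = FALSE)
}

test_that("single-stratum folds are perfectly balanced", {
  man <- make_manifest(10)
  fp <- stratified_folds(man, k = 5, seed = 1L)
  expect_identical(tabulate(fp$fold + 1L, nbins = 5), rep(2L, 5))
  expect_identical(sort(names(fp$fold)), sort(man$case_id))

  man7 <- make_manifest(7)
  fp7 <- stratified_folds(man7, k = 5, seed = 1L)
  counts <- tabulate(fp7$fold + 1L, nbins = 5)
  expect_identical(sort(counts), c(1L, 1L, 1L, 2L, 2L))
})

test_that("fold plans are deterministic and lesion-atomic", {
  man <- make_manifest(40, strata = 4L)
  a <- stratified_folds(man, k = 5, seed = 3L)
  b <- stratified_folds(man, k = 5, seed = 3L)
  expect_identical(a$fold, b$fold)
  expect_identical(length(a$fold), 40L)          # each lesion exactly once
  expect_true(all(names(a$fold) == man$case_id))
  expect_error(stratified_folds(make_manifest(3), k = 5),
               class = "dceseg_config_error")
})

test_that("every stratum is balanced within one lesion across folds", {
  man <- make_manifest(83, strata = 6L)
  fp <- stratified_folds(man, k = 5, seed = 2L)
  stratum <- interaction(man$pathology, man$enhancement_type, man$size_bin,
                         drop = TRUE)
  for (s in levels(stratum)) {
    counts <- tabulate(fp$fold[stratum == s] + 1L, nbins = 5)
    expect_lte(max(counts) - min(counts), 1L)
  }
})

test_that("signed-rank p-values match hand-enumerated cases", {
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_identical(res$statistic, 6)
  expect_equal(res$p_value, 0.25)
  expect_identical(res$method, "exact")

  expect_error(wilcoxon_signed_rank(1:4, 1:4), class = "dceseg_degenerate_test")
})

test_that("exact signed-rank matches full sign enumeration on random samples", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), sample(0:1, 1))   # rounding produces ties and zeros
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle_signed_rank_p(x, y),
                 tolerance = 1e-12, info = paste("rep", i))
  }
})

test_that("exact signed-rank agrees with stats::wilcox.test without ties", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)$p_value
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("exact and approximate signed-rank agree near the switch point", {
  set.seed(4)
  x <- rnorm(25); y <- rnorm(25)
  p_exact <- wilcoxon_signed_rank(x, y, exact_max = 25)$p_value
  p_norm <- wilcoxon_signed_rank(x, y, exact_max = 0)$p_value
  expect_lt(abs(p_exact - p_norm), 0.02)
})

test_that("Mann-Whitney p-values match enumeration and the reference test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  same <- mann_whitney_u(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p_value, 0.9)

  expect_error(mann_whitney_u(1:3, numeric(0)), class = "dceseg_config_error")

  set.seed(41)
  for (i in 1:50) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_p(x, y),
                 tolerance = 1e-12, info = paste("rep", i))
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mann_whitney_u(x, y)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0.02, 2), 0.04)
  expect_error(bonferroni(1.2, 2), class = "dceseg_value_error")
  expect_error(bonferroni(0.2, 0), class = "dceseg_value_error")

  set.seed(6)
  p <- runif(50); m <- sample(1:6, 50, replace = TRUE)
  q <- bonferroni(p, 1)  # m = 1 leaves p unchanged
  expect_identical(q, p)
  for (i in 1:50) {
    ci <- bonferroni(p[i], m[i])
    expect_gte(ci, p[i]); expect_lte(ci, 1)
  }
})

test_that("metric summaries report robust statistics with bootstrap CIs", {
  sm <- summarize_metric(c(0.2, 0.5, 0.8), seed = 1L)
  expect_equal(sm$median, 0.5)
  expect_identical(sm$n, 3L)

  same <- summarize_metric(rep(0.7, 10))
  expect_identical(same$ci95, c(0.7, 0.7))

  withNA <- summarize_metric(c(1, 2, NA, 4), seed = 2L)
  expect_identical(withNA$n_excluded, 1L)
  expect_error(summarize_metric(c(NA_real_, NA_real_)),
               class = "dceseg_empty_summary")
})

test_that("bootstrap CIs cover the true median at nominal-ish rate", {
  true_med <- qnorm(0.5, mean = 3)   # 3
  hits <- vapply(1:100, function(r) {
    v <- with_seed(1000L + r, rnorm(300, mean = 3))
    sm <- summarize_metric(v, n_boot = 400L, seed = r)
    sm$ci95[1] <= true_med && true_med <= sm$ci95[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
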