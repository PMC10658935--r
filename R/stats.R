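# Cross-validation fold construction and nonparametric test machinery.

#' Stratified by-lesion fold plan
#'
#' Lesions are assigned whole (never slice-wise) to `k` folds so that every
#' stratum — pathology x enhancement type x size bin — is spread as evenly as
#' possible: within each stratum the fold counts differ by at most one.
#' Strata are processed largest first; lesions are shuffled inside each
#' stratum with the given seed and dealt to folds ordered by current load.
#'
#' @param manifest data.frame with columns `case_id`, `pathology`,
#'   `enhancement_type`, `size_bin`.
#' @param k number of folds (>= 2, <= number of lesions).
#' @param seed shuffling seed.
#' @return object of class `fold_plan`: `fold` (named integer vector, values
#'   in 0..k-1, names = case_id), `k`, `seed`, and `strata` (per-fold
#'   stratum counts).
#' @export
stratified_folds <- function(manifest, k = 5L, seed = 1L) {
  n <- nrow(manifest)
  if (k < 2L) stop_dceseg("k must be >= 2", "dceseg_config_error")
  if (k > n) stop_dceseg("more folds than lesions", "dceseg_config_error")
  stratum <- interaction(manifest$pathology, manifest$enhancement_type,
                         manifest$size_bin, drop = TRUE)
  fold <- integer(n)
  names(fold) <- manifest$case_id
  load <- integer(k)
  with_seed(seed, {
    for (s in names(sort(table(stratum), decreasing = TRUE))) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      ord <- order(load, sample.int(k))      # least-loaded folds first, random ties
      assign_fold <- rep(ord - 1L, length.out = length(idx))
      fold[idx] <- assign_fold
      load <- load + tabulate(assign_fold + 1L, nbins = k)
    }
  })
  strata_tab <- table(stratum, factor(fold, levels = 0:(k - 1L)))
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed),
                 strata = strata_tab),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d lesions in %d folds (seed %d)\n",
              length(x$fold), x$k, x$seed))
  print(table(factor(x$fold, levels = 0:(x$k - 1L))))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W+ for (possibly
# tie-averaged) ranks r: generating-function convolution over doubled ranks,
# equivalent to enumerating all 2^n sign assignments.
signed_rank_null <- function(ranks2) {
  counts <- c(1)                       # counts[w + 1] = #assignments with 2*W+ = w
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  counts
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped; tied absolute differences receive averaged
#' ranks. For n <= `exact_max` retained pairs the p-value is computed from
#' the exact null distribution of W+ (equivalent to enumerating every sign
#' assignment); above that, a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (W+), `p_value`, `n` (retained pairs),
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y))
    stop_dceseg("paired samples must have equal length", "dceseg_value_error")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop_dceseg("all differences are zero; test degenerate", "dceseg_degenerate_test")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    counts <- signed_rank_null(as.integer(round(2 * r)))
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p-value from the null distribution of U when both samples are
#' tie-free and `length(x) * length(y) <= exact_max_product`; otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (unmatched groups), both non-empty.
#' @param exact_max_product exactness cutoff on `n * m`.
#' @return list with `statistic` (U of the first sample), `p_value`, `n`,
#'   `m`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max_product = 400L) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0)
    stop_dceseg("both groups must be non-empty", "dceseg_config_error")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n * m <= exact_max_product) {
    counts <- mw_null_distribution(n, m)
    total <- sum(counts)
    ui <- as.integer(round(u))
    p_le <- sum(counts[seq_len(ui + 1L)]) / total
    p_ge <- sum(counts[(ui + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * m / 2
    nt <- n + m
    ties <- table(r)
    sigma2 <- n * m / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = u, p_value = p, n = n, m = m, method = method)
}

# Distribution of U for sample sizes (n, m) without ties, by the standard
# recurrence N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1).
mw_null_distribution <- function(n, m) {
  maxu <- n * m
  # dp[[i]] over j built iteratively; store counts vector indexed by u + 1
  prev <- vector("list", m + 1L)
  for (j in 0:m) prev[[j + 1L]] <- c(1, rep(0, maxu))   # n = 0
  for (i in seq_len(n)) {
    cur <- vector("list", m + 1L)
    cur[[1L]] <- c(1, rep(0, maxu))                      # m = 0
    for (j in seq_len(m)) {
      a <- prev[[j + 1L]]                                # N(u - j; i - 1, j)
      shifted <- c(rep(0, j), a[seq_len(maxu + 1L - j)])
      cur[[j + 1L]] <- shifted + cur[[j]]                # + N(u; i, j - 1)
    }
    prev <- cur
  }
  prev[[m + 1L]]
}

#' Bonferroni correction
#' @param raw_p raw p-value(s) in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return `min(1, raw_p * m)`.
#' @export
bonferroni <- function(raw_p, m) {
  if (any(raw_p < 0 | raw_p > 1)) stop_dceseg("p must be in [0, 1]", "dceseg_value_error")
  if (m < 1) stop_dceseg("m must be >= 1", "dceseg_value_error")
  pmin(1, raw_p * m)
}

#' Summary of a metric with a bootstrap CI for the median
#'
#' Minimum, maximum and median of the defined (non-NA) values, plus a seeded
#' percentile-bootstrap 95% confidence interval for the median.
#'
#' @param values numeric vector; NAs (undefined Hausdorff distances of failed
#'   segmentations) are excluded and counted.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `min`, `max`, `median`, `ci95` (length-2), `n`,
#'   `n_excluded`.
#' @export
summarize_metric <- function(values, n_boot = 2000L, seed = 1L) {
  n_excluded <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (!length(v)) stop_dceseg("no defined values to summarize", "dceseg_empty_summary")
  med <- stats::median(v)
  ci <- if (length(unique(v)) == 1L) c(v[1], v[1]) else with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i)
      stats::median(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    unname(stats::quantile(boots, c(0.025, 0.975)))
  })
  list(min = min(v), max = max(v), median = med, ci95 = ci,
       n = length(v), n_excluded = n_excluded)
}
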