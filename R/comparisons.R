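# The four benchmark comparisons between segmentation arms.
#
# A: quasi-3D vs 3D U-Net volume segmentations against the FCM surrogate
#    reference (paired Wilcoxon signed-rank; Bonferroni m = 2).
# B: FCM, quasi-3D and 3D center-slice segmentations against the
#    center-slice truth reference (three pairwise signed-rank tests per
#    metric; m = 3).
# C: first vs second postcontrast subtraction inputs, per U-Net arm
#    (paired signed-rank; m = 4).
# D: mass vs nonmass lesions, per U-Net arm and timepoint
#    (unpaired Mann-Whitney U; m = 4).
#
# Lesions whose Hausdorff distance is undefined (failed segmentations) are
# excluded from HD tests and listed; they keep DSC = 0 in DSC tests.

comparison_row <- function(comparison, metric, group1, group2, test, n,
                           direction, excluded) {
  data.frame(comparison = comparison, metric = metric, group1 = group1,
             group2 = group2, n = n,
             raw_p = if (is.null(test)) NA_real_ else test$p_value,
             corrected_p = NA_real_,
             test = if (is.null(test)) "degenerate" else test$method,
             direction = direction,
             n_excluded = length(excluded),
             excluded_ids = paste(excluded, collapse = ";"),
             stringsAsFactors = FALSE)
}

# Paired test on a metric column between two record subsets matched by
# lesion_id. `higher_better` fixes the direction wording.
paired_metric_test <- function(rec1, rec2, column, label1, label2,
                               comparison, metric, higher_better) {
  common <- intersect(rec1$lesion_id, rec2$lesion_id)
  v1 <- rec1[[column]][match(common, rec1$lesion_id)]
  v2 <- rec2[[column]][match(common, rec2$lesion_id)]
  ok <- !is.na(v1) & !is.na(v2)
  excluded <- common[!ok]
  v1 <- v1[ok]; v2 <- v2[ok]
  if (!length(v1))
    return(comparison_row(comparison, metric, label1, label2, NULL, 0L,
                          "inconclusive", excluded))
  test <- tryCatch(wilcoxon_signed_rank(v1, v2),
                   dceseg_degenerate_test = function(e) NULL)
  d <- stats::median(v1) - stats::median(v2)
  direction <- if (d == 0) "tie"
               else if ((d > 0) == higher_better) paste(label1, "better")
               else paste(label2, "better")
  comparison_row(comparison, metric, label1, label2, test, length(v1),
                 if (is.null(test)) "inconclusive" else direction, excluded)
}

unpaired_metric_test <- function(rec1, rec2, column, label1, label2,
                                 comparison, metric, higher_better) {
  v1 <- rec1[[column]]; v2 <- rec2[[column]]
  ex1 <- rec1$lesion_id[is.na(v1)]; ex2 <- rec2$lesion_id[is.na(v2)]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (!length(v1) || !length(v2))
    return(comparison_row(comparison, metric, label1, label2, NULL,
                          length(v1) + length(v2), "inconclusive", c(ex1, ex2)))
  test <- tryCatch(mann_whitney_u(v1, v2), dceseg_config_error = function(e) NULL)
  d <- stats::median(v1) - stats::median(v2)
  direction <- if (d == 0) "tie"
               else if ((d > 0) == higher_better) paste(label1, "better")
               else paste(label2, "better")
  comparison_row(comparison, metric, label1, label2, test, length(v1) + length(v2),
                 direction, c(ex1, ex2))
}

sub_records <- function(records, method = NULL, reference = NULL, timepoint = NULL,
                        enhancement_type = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(method)) keep <- keep & records$method == method
  if (!is.null(reference)) keep <- keep & records$reference == reference
  if (!is.null(timepoint)) keep <- keep & records$timepoint == timepoint
  if (!is.null(enhancement_type))
    keep <- keep & records$enhancement_type == enhancement_type
  records[keep, , drop = FALSE]
}

#' Run one of the four arm comparisons
#'
#' @param design `"A"`, `"B"`, `"C"` or `"D"`.
#' @param records metric table (rows from [evaluate_lesion()]): per-lesion
#'   DSC/HD for each (method, reference, timepoint) combination.
#' @param m_corrections Bonferroni correction count; defaults per design
#'   (A: 2, B: 3, C: 4, D: 4).
#' @return data.frame of comparison results with raw and corrected p-values,
#'   the better-performing arm by median, and excluded lesion ids
#'   (undefined HD).
#' @export
run_comparison <- function(design = c("A", "B", "C", "D"), records,
                           m_corrections = NULL) {
  design <- match.arg(design)
  m <- m_corrections %||% c(A = 2L, B = 3L, C = 4L, D = 4L)[[design]]
  rows <- switch(design,
    A = {
      q <- sub_records(records, "quasi3d", "fcm", 2L)
      u <- sub_records(records, "unet3d", "fcm", 2L)
      if (!nrow(q) || !nrow(u))
        stop_dceseg("comparison A needs quasi3d and unet3d records against the fcm reference",
                    "dceseg_config_error")
      list(
        paired_metric_test(q, u, "dsc", "quasi3d", "unet3d", "A", "DSC", TRUE),
        paired_metric_test(q, u, "median_hd_mm", "quasi3d", "unet3d", "A", "HD", FALSE))
    },
    B = {
      arms <- list(fcm = sub_records(records, "fcm", "truth", 2L),
                   quasi3d = sub_records(records, "quasi3d", "truth", 2L),
                   unet3d = sub_records(records, "unet3d", "truth", 2L))
      if (any(vapply(arms, nrow, 0L) == 0L))
        stop_dceseg("comparison B needs fcm, quasi3d and unet3d center-slice records against truth",
                    "dceseg_config_error")
      pairs <- list(c("fcm", "quasi3d"), c("quasi3d", "unet3d"), c("fcm", "unet3d"))
      out <- list()
      for (pr in pairs) {
        out[[length(out) + 1L]] <- paired_metric_test(
          arms[[pr[1]]], arms[[pr[2]]], "center_dsc", pr[1], pr[2], "B", "DSC", TRUE)
        out[[length(out) + 1L]] <- paired_metric_test(
          arms[[pr[1]]], arms[[pr[2]]], "center_hd_mm", pr[1], pr[2], "B", "HD", FALSE)
      }
      out
    },
    C = {
      out <- list()
      for (meth in c("quasi3d", "unet3d")) {
        t1 <- sub_records(records, meth, "fcm", 1L)
        t2 <- sub_records(records, meth, "fcm", 2L)
        if (!nrow(t1) || !nrow(t2)) next
        out[[length(out) + 1L]] <- paired_metric_test(
          t2, t1, "dsc", paste0(meth, "@post2"), paste0(meth, "@post1"), "C", "DSC", TRUE)
        out[[length(out) + 1L]] <- paired_metric_test(
          t2, t1, "median_hd_mm", paste0(meth, "@post2"), paste0(meth, "@post1"), "C", "HD", FALSE)
      }
      if (!length(out))
        stop_dceseg("comparison C needs records at both postcontrast timepoints",
                    "dceseg_config_error")
      out
    },
    D = {
      out <- list()
      for (meth in c("quasi3d", "unet3d")) for (tp in c(1L, 2L)) {
        rec <- sub_records(records, meth, "fcm", tp)
        if (!nrow(rec)) next
        ms <- sub_records(rec, enhancement_type = "mass")
        nm <- sub_records(rec, enhancement_type = "nonmass")
        if (!nrow(ms) || !nrow(nm)) next
        lab <- sprintf("%s@post%d", meth, tp)
        out[[length(out) + 1L]] <- unpaired_metric_test(
          ms, nm, "dsc", paste0(lab, ":mass"), paste0(lab, ":nonmass"), "D", "DSC", TRUE)
        out[[length(out) + 1L]] <- unpaired_metric_test(
          ms, nm, "median_hd_mm", paste0(lab, ":mass"), paste0(lab, ":nonmass"), "D", "HD", FALSE)
      }
      if (!length(out))
        stop_dceseg("comparison D needs mass and nonmass records", "dceseg_config_error")
      out
    })
  res <- do.call(rbind, rows)
  res$corrected_p <- ifelse(is.na(res$raw_p), NA_real_, bonferroni(ifelse(is.na(res$raw_p), 0, res$raw_p), m))
  res$m_corrections <- m
  res
}
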