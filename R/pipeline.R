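# Experiment orchestration: simulate a cohort, build the FCM surrogate
# reference, train and apply both U-Net arms at the requested timepoints
# under a by-lesion fold plan, evaluate all arms, and run the four
# comparisons.

#' Plan a full benchmark experiment
#'
#' @param n cohort size.
#' @param composition stratum composition table (see [generate_cohort()]).
#' @param protocol a [dce_protocol()].
#' @param folds by-lesion cross-validation folds (2 trains on half the
#'   cohort and tests every lesion once; 5 mirrors the clinical design).
#' @param arms segmentation arms to run.
#' @param timepoints postcontrast subtraction inputs for the U-Net arms.
#' @param unet2d,unet3d [unet_config()] objects for the two arms.
#' @param epochs2d,epochs3d training epochs per arm.
#' @param train_reference `"fcm"` (the surrogate-reference convention) or
#'   `"truth"` — which masks supervise U-Net training.
#' @param calibrate if `TRUE`, sweep the threshold grid on training-fold
#'   predictions per arm instead of using the configured thresholds.
#' @param threshold_grid candidate thresholds for calibration.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(n = 60L, composition = default_composition(),
                            protocol = dce_protocol(), folds = 5L,
                            arms = c("fcm", "quasi3d", "unet3d"),
                            timepoints = c(1L, 2L),
                            unet2d = unet_config("2d"),
                            unet3d = unet_config("3d"),
                            epochs2d = 30L, epochs3d = 30L,
                            train_reference = c("fcm", "truth"),
                            calibrate = FALSE,
                            threshold_grid = seq(0.14, 0.30, by = 0.01),
                            seed = 1L, out_dir = NULL) {
  train_reference <- match.arg(train_reference)
  arms <- match.arg(arms, c("fcm", "quasi3d", "unet3d"), several.ok = TRUE)
  structure(list(n = as.integer(n), composition = composition,
                 protocol = protocol, folds = as.integer(folds), arms = arms,
                 timepoints = as.integer(timepoints), unet2d = unet2d,
                 unet3d = unet3d, epochs2d = as.integer(epochs2d),
                 epochs3d = as.integer(epochs3d),
                 train_reference = train_reference, calibrate = calibrate,
                 threshold_grid = threshold_grid, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_plan")
}

# Which comparisons the planned arms/timepoints can support.
plan_supports <- function(plan) {
  has2 <- "quasi3d" %in% plan$arms && 2L %in% plan$timepoints
  has3 <- "unet3d" %in% plan$arms && 2L %in% plan$timepoints
  c(A = has2 && has3,
    B = "fcm" %in% plan$arms && has2 && has3,
    C = (("quasi3d" %in% plan$arms) || ("unet3d" %in% plan$arms)) &&
        all(c(1L, 2L) %in% plan$timepoints),
    D = has2 || has3)
}

#' Run a planned experiment end to end
#'
#' Generates the cohort, segments every lesion with FCM (surrogate
#' reference), builds the stratified by-lesion fold plan, trains the 2D and
#' 3D U-Net arms per fold and timepoint on held-in lesions, predicts the
#' held-out lesions, resizes predictions back to the VOI grids, evaluates
#' volume and center-slice metrics, and runs the supported comparisons.
#'
#' @param plan an [experiment_plan()].
#' @param comparisons which of A-D to run (defaults to all the plan
#'   supports); requesting an unsupported one is an error.
#' @param verbose log stage progress to stderr.
#' @return list with `manifest`, `fold_plan`, `records` (metric table),
#'   `comparisons` (named list of result tables), `summaries` (per-arm
#'   median summaries), `thresholds`, `config_hash`.
#' @export
run_experiment <- function(plan, comparisons = NULL, verbose = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  supported <- plan_supports(plan)
  comparisons <- comparisons %||% names(supported)[supported]
  if (any(!supported[comparisons]))
    stop_dceseg(sprintf("plan cannot support comparison(s): %s",
                        paste(comparisons[!supported[comparisons]], collapse = ", ")),
                "dceseg_dependency_error")
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(plan[setdiff(names(plan), "out_dir")])
  say("experiment config %s (seed %d)", hash, plan$seed)

  say("generating cohort (n = %d)", plan$n)
  cohort <- generate_cohort(plan$n, plan$composition, plan$protocol,
                            seed = plan$seed)
  cases <- cohort$cases
  manifest <- cohort$manifest

  say("FCM surrogate reference segmentation")
  fcm_masks <- lapply(cases, function(cs)
    segment_fcm(cs, seed = plan$seed + 17L))
  fcm_ok <- !vapply(fcm_masks, function(m) m$failed, logical(1))

  fp <- stratified_folds(manifest, k = plan$folds, seed = plan$seed + 29L)

  train_masks <- if (plan$train_reference == "fcm") fcm_masks
                 else lapply(cases, truth_mask_voi)

  # per-arm, per-timepoint held-out predictions across folds
  thresholds <- list(quasi3d = plan$unet2d$threshold, unet3d = plan$unet3d$threshold)
  preds <- list()
  for (arm in intersect(plan$arms, c("quasi3d", "unet3d"))) {
    for (tp in plan$timepoints) {
      key <- sprintf("%s_tp%d", arm, tp)
      preds[[key]] <- vector("list", plan$n)
      for (f in 0:(plan$folds - 1L)) {
        tr_idx <- which(fp$fold[manifest$case_id] != f & fcm_ok)
        te_idx <- which(fp$fold[manifest$case_id] == f)
        say("training %s (timepoint %d, fold %d: %d train / %d test lesions)",
            arm, tp, f, length(tr_idx), length(te_idx))
        seed_f <- plan$seed + 1000L * match(arm, c("quasi3d", "unet3d")) +
          100L * tp + f
        if (arm == "quasi3d") {
          samp <- make_2d_training_set(cases[tr_idx], train_masks[tr_idx], tp,
                                       plan$unet2d$input_size)
          model <- train_unet(samp, plan$unet2d, epochs = plan$epochs2d,
                              seed = seed_f)
        } else {
          samp <- make_3d_training_set(cases[tr_idx], train_masks[tr_idx], tp,
                                       plan$unet3d$input_size)
          model <- train_unet(samp, plan$unet3d, epochs = plan$epochs3d,
                              seed = seed_f)
        }
        if (plan$calibrate && f == 0L) {
          cal <- calibrate_arm(model, cases[tr_idx], train_masks[tr_idx], tp,
                               plan$threshold_grid)
          thresholds[[arm]] <- cal$selected
          say("calibrated %s threshold: %.2f", arm, cal$selected)
        }
        for (i in te_idx) {
          preds[[key]][[i]] <- predict_arm(model, cases[[i]], tp,
                                           thresholds[[arm]])
        }
      }
    }
  }

  say("evaluating")
  records <- evaluate_experiment(cases, manifest, fcm_masks, preds, plan)

  out_comp <- list()
  for (cmp in comparisons) {
    out_comp[[cmp]] <- tryCatch(run_comparison(cmp, records),
                                dceseg_config_error = function(e) NULL)
  }

  summaries <- summarize_records(records, seed = plan$seed)

  result <- list(manifest = manifest, fold_plan = fp, records = records,
                 comparisons = out_comp, summaries = summaries,
                 thresholds = thresholds, config_hash = hash)
  if (!is.null(plan$out_dir)) write_experiment(result, plan$out_dir)
  result
}

# Predict one case with a trained arm and bring the mask back to the VOI grid.
predict_arm <- function(model, case, tp, threshold) {
  if (model$config$arch == "2d") {
    prob_slices <- predict_slices(model, case, timepoint = tp)
    prob <- array(0, c(dim(prob_slices[[1]]), length(prob_slices)))
    for (k in seq_along(prob_slices)) prob[, , k] <- prob_slices[[k]]
    resize_prediction_to_voi(prob, case$voi, case$spacing_mm, threshold,
                             method = "quasi3d")
  } else {
    prob <- predict_3d_probability(model, case, timepoint = tp)
    resize_prediction_to_voi(prob, case$voi, case$spacing_mm, threshold,
                             method = "unet3d")
  }
}

# Threshold calibration on training-fold predictions.
calibrate_arm <- function(model, cases, refs, tp, grid) {
  probs <- list(); targets <- list()
  for (i in seq_along(cases)) {
    if (model$config$arch == "2d") {
      ps <- predict_slices(model, cases[[i]], timepoint = tp)
      prob <- array(0, c(dim(ps[[1]]), length(ps)))
      for (k in seq_along(ps)) prob[, , k] <- ps[[k]]
    } else {
      prob <- predict_3d_probability(model, cases[[i]], timepoint = tp)
    }
    sz <- dim(prob)[1]
    ref <- as_mask_array(refs[[i]])
    tgt <- array(0, dim(prob))
    for (k in seq_len(dim(prob)[3]))
      tgt[, , k] <- resize_nearest(ref[, , k] * 1, sz, sz)
    probs[[i]] <- prob; targets[[i]] <- tgt
  }
  calibrate_threshold(probs, targets, grid)
}

evaluate_experiment <- function(cases, manifest, fcm_masks, preds, plan) {
  rows <- list()
  truth_masks <- lapply(cases, truth_mask_voi)
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    strata <- manifest[i, c("pathology", "enhancement_type", "size_bin")]
    # U-Net arms against the FCM surrogate reference (volume + center)
    if (!fcm_masks[[i]]$failed) {
      for (key in names(preds)) {
        pred <- preds[[key]][[i]]
        if (is.null(pred)) next
        arm <- sub("_tp[0-9]+$", "", key)
        tp <- as.integer(sub("^.*_tp", "", key))
        rows[[length(rows) + 1L]] <- evaluate_lesion(
          pred, fcm_masks[[i]], case$voi, case$spacing_mm,
          lesion_id = case$case_id, method = arm, reference = "fcm",
          timepoint = tp, strata = strata)
      }
    }
    # center-slice agreement with truth (the synthetic stand-in for expert
    # center-slice delineations), at the second postcontrast timepoint
    arms_b <- c(list(fcm = fcm_masks[[i]]),
                stats::setNames(
                  lapply(intersect(names(preds), c("quasi3d_tp2", "unet3d_tp2")),
                         function(k) preds[[k]][[i]]),
                  sub("_tp2$", "", intersect(names(preds), c("quasi3d_tp2", "unet3d_tp2")))))
    for (arm in names(arms_b)) {
      pred <- arms_b[[arm]]
      if (is.null(pred)) next
      rows[[length(rows) + 1L]] <- evaluate_lesion(
        pred, truth_masks[[i]], case$voi, case$spacing_mm,
        lesion_id = case$case_id, method = arm, reference = "truth",
        timepoint = 2L, strata = strata)
    }
  }
  do.call(rbind, rows)
}

summarize_records <- function(records, seed = 1L) {
  keys <- unique(records[, c("method", "reference", "timepoint")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    rec <- sub_records(records, keys$method[r], keys$reference[r], keys$timepoint[r])
    sm_d <- summarize_metric(rec$dsc, seed = seed)
    sm_h <- tryCatch(summarize_metric(rec$median_hd_mm, seed = seed),
                     dceseg_empty_summary = function(e) NULL)
    out[[length(out) + 1L]] <- data.frame(
      method = keys$method[r], reference = keys$reference[r],
      timepoint = keys$timepoint[r], n = sm_d$n,
      median_dsc = sm_d$median, dsc_ci_lo = sm_d$ci95[1], dsc_ci_hi = sm_d$ci95[2],
      median_hd_mm = if (is.null(sm_h)) NA_real_ else sm_h$median,
      n_hd_excluded = if (is.null(sm_h)) sm_d$n else sm_h$n_excluded,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

write_experiment <- function(result, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_dceseg("cannot create output directory", "dceseg_io_error")
  utils::write.csv(result$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(result$records, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(result$summaries, file.path(out_dir, "summaries.csv"), row.names = FALSE)
  for (cmp in names(result$comparisons))
    if (!is.null(result$comparisons[[cmp]]))
      utils::write.csv(result$comparisons[[cmp]],
                       file.path(out_dir, sprintf("comparison_%s.csv", cmp)),
                       row.names = FALSE)
  jsonlite::write_json(
    list(fold = as.list(result$fold_plan$fold), k = result$fold_plan$k,
         seed = result$fold_plan$seed, config_hash = result$config_hash,
         thresholds = result$thresholds),
    file.path(out_dir, "fold_plan.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
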