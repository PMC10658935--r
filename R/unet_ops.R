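# Preprocessing, prediction, quasi-3D assembly and threshold calibration
# for the U-Net arms.

# Crop a subtraction volume and a reference mask to the VOI grid.
voi_subtraction <- function(case, timepoint) {
  crop_to_voi(subtraction_image(case, timepoint), case$voi)
}

#' Build the 2D (slice) training set
#'
#' For each lesion the VOI subtraction image at the requested postcontrast
#' timepoint is cropped, each slice resized (range-preservingly) to the
#' network input size, and paired with the reference mask slice (nearest-
#' neighbour resize). The top and bottom VOI slices — the hardest to
#' segment — are excluded from training whenever the lesion has at least 3
#' VOI slices; thinner lesions keep all slices (flagged in the sample).
#' Test-set prediction always covers every slice.
#'
#' @param cases list of `dce_case`.
#' @param ref_masks list of reference `dce_mask`s on the matching VOI grids
#'   (e.g. FCM segmentations, the surrogate reference used for training).
#' @param timepoint postcontrast subtraction index (1 or 2).
#' @param input_size network input size.
#' @return list of slice samples: `image`, `target`, `lesion_id`,
#'   `slice_index` (VOI-grid index), `kept_all_slices`.
#' @export
make_2d_training_set <- function(cases, ref_masks, timepoint, input_size = 256L) {
  out <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    ref <- as_mask_array(ref_masks[[i]])
    sub <- voi_subtraction(case, timepoint)
    if (!identical(dim(sub), dim(ref)))
      stop_dceseg("reference mask not on the case VOI grid", "dceseg_integrity_error")
    ns <- dim(sub)[3]
    keep <- if (ns >= 3L) 2L:(ns - 1L) else seq_len(ns)
    vol_range <- range(sub)    # per-VOI normalization anchor for net input
    for (k in keep) {
      out[[length(out) + 1L]] <- list(
        image = resize_bilinear(sub[, , k], input_size, input_size),
        target = resize_nearest(ref[, , k] * 1, input_size, input_size),
        norm_range = vol_range,
        lesion_id = case$case_id, slice_index = k,
        kept_all_slices = ns < 3L)
    }
  }
  out
}

#' Build the 3D (volume) training set
#'
#' The VOI subtraction volume is resized in-plane to `input_size` x
#' `input_size` x N (N = the lesion's VOI slice count; no axial resampling),
#' paired with the nearest-neighbour-resized reference volume.
#'
#' @inheritParams make_2d_training_set
#' @return list of volume samples: `image`, `target`, `lesion_id`.
#' @export
make_3d_training_set <- function(cases, ref_masks, timepoint, input_size = 256L) {
  lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    ref <- as_mask_array(ref_masks[[i]])
    sub <- voi_subtraction(case, timepoint)
    if (!identical(dim(sub), dim(ref)))
      stop_dceseg("reference mask not on the case VOI grid", "dceseg_integrity_error")
    ns <- dim(sub)[3]
    img <- array(0, c(input_size, input_size, ns))
    tgt <- array(0, c(input_size, input_size, ns))
    for (k in seq_len(ns)) {
      img[, , k] <- resize_bilinear(sub[, , k], input_size, input_size)
      tgt[, , k] <- resize_nearest(ref[, , k] * 1, input_size, input_size)
    }
    list(image = img, target = tgt, lesion_id = case$case_id)
  })
}

#' Predict per-slice probability maps with the 2D arm
#'
#' All VOI slices are predicted, including the top and bottom slices that
#' training excluded.
#'
#' @param model a trained 2D `dce_unet`.
#' @param case a `dce_case`.
#' @param voi VOI (defaults to the case VOI).
#' @param timepoint postcontrast subtraction index.
#' @return list of probability matrices (input_size^2), one per VOI slice,
#'   ordered by slice index.
#' @export
predict_slices <- function(model, case, voi = case$voi, timepoint = 2L) {
  if (!inherits(model, "dce_unet") || model$config$arch != "2d")
    stop_dceseg("model is not a trained 2D U-Net", "dceseg_state_error")
  sz <- model$config$input_size
  sub <- crop_to_voi(subtraction_image(case, timepoint), voi)
  ns <- dim(sub)[3]
  x <- array(0, c(sz, sz, ns, 1L))
  for (k in seq_len(ns))
    x[, , k, 1L] <- resize_bilinear(sub[, , k], sz, sz)
  x <- normalize01(x)          # per-VOI normalization, as in training
  prob <- unet_probability(model, x)
  lapply(seq_len(ns), function(k) prob[, , k, 1L])
}

#' Assemble a quasi-3D segmentation from 2D slice probabilities
#'
#' Stacks the slice-by-slice probability maps of the 2D arm and thresholds
#' them into a binary volume ("quasi-3D U-Net"). An all-empty result is
#' flagged failed.
#'
#' @param prob_slices list of probability matrices ordered by slice index.
#' @param threshold binarization threshold in (0, 1); 0.25 is the calibrated
#'   default for the 2D arm.
#' @param voi,spacing_mm carried onto the returned mask.
#' @return a [segmentation_mask()] on the network grid (method "quasi3d").
#' @export
assemble_quasi3d <- function(prob_slices, threshold = 0.25, voi = NULL,
                             spacing_mm = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop_dceseg("threshold must be in (0, 1)", "dceseg_value_error")
  d <- dim(prob_slices[[1]])
  vol <- array(FALSE, c(d[1], d[2], length(prob_slices)))
  for (k in seq_along(prob_slices)) vol[, , k] <- prob_slices[[k]] > threshold
  segmentation_mask(vol, voi, spacing_mm, method = "quasi3d")
}

#' Predict a 3D segmentation with the 3D arm
#'
#' The VOI subtraction volume (in-plane resized, axially untouched) is
#' passed through the 3D network and thresholded. With axial pooling
#' enabled, volumes are zero-padded to an even slice count and cropped back.
#'
#' @param model a trained 3D `dce_unet`.
#' @param case a `dce_case`.
#' @param voi VOI; defaults to the case VOI.
#' @param timepoint postcontrast subtraction index.
#' @param threshold binarization threshold in (0, 1); 0.23 is the calibrated
#'   default for the 3D arm.
#' @return a [segmentation_mask()] on the network grid (method "unet3d").
#' @export
predict_3d <- function(model, case, voi = case$voi, timepoint = 2L,
                       threshold = 0.23) {
  if (!inherits(model, "dce_unet") || model$config$arch != "3d")
    stop_dceseg("model is not a trained 3D U-Net", "dceseg_state_error")
  if (threshold <= 0 || threshold >= 1)
    stop_dceseg("threshold must be in (0, 1)", "dceseg_value_error")
  prob <- predict_3d_probability(model, case, voi, timepoint)
  segmentation_mask(prob > threshold, voi, case$spacing_mm, method = "unet3d")
}

# Probability volume of the 3D arm (input_size x input_size x N).
predict_3d_probability <- function(model, case, voi = case$voi, timepoint = 2L) {
  sz <- model$config$input_size
  sub <- crop_to_voi(subtraction_image(case, timepoint), voi)
  ns <- dim(sub)[3]
  img <- array(0, c(sz, sz, ns))
  for (k in seq_len(ns)) img[, , k] <- resize_bilinear(sub[, , k], sz, sz)
  x <- array(normalize01(img), c(sz, sz, ns, 1L))
  pad_to <- if (model$config$axial_pool) 2L^(model$config$levels - 1L) else 1L
  ns_pad <- ceiling(ns / pad_to) * pad_to
  if (ns_pad > ns) {
    xp <- array(0, c(sz, sz, ns_pad, 1L))
    xp[, , seq_len(ns), ] <- x
    x <- xp
  }
  prob <- unet_probability(model, x)
  array(prob[, , seq_len(ns), 1L], c(sz, sz, ns))
}

#' Calibrate the binarization threshold on training predictions
#'
#' Evaluates every candidate threshold on (probability map, reference mask)
#' pairs and selects the one maximizing the mean Dice similarity
#' coefficient; ties go to the smallest threshold. During the sweep, values
#' equal to the candidate threshold count as foreground (the sweep is
#' right-continuous in the threshold); the final binarization operators use
#' a strict `>`. The default grid is the 0.14-0.30 sweep (step 0.01) used
#' to calibrate the 0.25 (2D) and 0.23 (3D) operating points.
#'
#' @param prob_maps list of probability arrays.
#' @param ref_masks list of binary arrays of matching shapes.
#' @param grid candidate thresholds.
#' @return object of class `threshold_calibration`: `grid`, `mean_dsc`,
#'   `selected`.
#' @export
calibrate_threshold <- function(prob_maps, ref_masks,
                                grid = seq(0.14, 0.30, by = 0.01)) {
  if (length(prob_maps) == 0 || length(prob_maps) != length(ref_masks))
    stop_dceseg("need matching, non-empty probability/reference lists",
                "dceseg_config_error")
  grid <- sort(grid)
  mean_dsc <- vapply(grid, function(th)
    mean(vapply(seq_along(prob_maps), function(i)
      dice(prob_maps[[i]] >= th, as_mask_array(ref_masks[[i]])), numeric(1))),
    numeric(1))
  best <- which(mean_dsc >= max(mean_dsc) - 1e-12)[1L]
  structure(list(grid = grid, mean_dsc = mean_dsc, selected = grid[best]),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> selected %.2f (mean DSC %.4f) over [%.2f, %.2f]\n",
              x$selected, x$mean_dsc[match(x$selected, x$grid)],
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Resize a network prediction back to the original VOI grid
#'
#' Probability maps are interpolated in-plane (plain bilinear, no range
#' rescaling) to the VOI's in-plane dimensions and then thresholded; binary
#' masks are resized nearest-neighbour. The slice count must already match
#' the VOI (the networks never resample axially).
#'
#' @param pred probability array (values in [0, 1]) or a `dce_mask` /
#'   binary array on the network grid.
#' @param voi the original [lesion_voi()].
#' @param spacing_mm named spacing of the original grid.
#' @param threshold threshold applied after interpolation of a probability
#'   map; ignored for binary input.
#' @param method label for the returned mask.
#' @return a [segmentation_mask()] on the VOI grid.
#' @export
resize_prediction_to_voi <- function(pred, voi, spacing_mm, threshold = 0.25,
                                     method = "prediction") {
  is_mask <- inherits(pred, "dce_mask")
  arr <- if (is_mask) pred$mask * 1 else pred
  nr <- voi$row_range[2] - voi$row_range[1] + 1L
  nc <- voi$col_range[2] - voi$col_range[1] + 1L
  ns <- voi$last_slice - voi$first_slice + 1L
  if (dim(arr)[3] != ns)
    stop_dceseg("slice count does not match the recorded VOI", "dceseg_integrity_error")
  out <- array(FALSE, c(nr, nc, ns))
  for (k in seq_len(ns)) {
    if (is_mask || all(arr[, , k] %in% c(0, 1))) {
      out[, , k] <- resize_nearest(arr[, , k], nr, nc) > 0.5
    } else {
      out[, , k] <- resize_bilinear(arr[, , k], nr, nc, preserve_range = FALSE) > threshold
    }
  }
  segmentation_mask(out, voi, spacing_mm, method = method)
}
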