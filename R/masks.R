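#' Binary segmentation mask on a VOI grid
#'
#' A 3D binary mask aligned to an operator VOI, carrying the voxel spacing
#' and a `failed` flag for empty segmentations (the failure mode in which a
#' segmenter produces no voxels for a lesion; such lesions contribute DSC = 0
#' and are excluded from Hausdorff statistics).
#'
#' @param mask logical/0-1 3D array on the VOI grid.
#' @param voi the [lesion_voi()] the grid is aligned to.
#' @param spacing_mm named `c(row, col, slice)` spacing in mm.
#' @param method label of the producing segmenter.
#' @return object of class `dce_mask`; `failed` is `TRUE` iff the mask is
#'   empty.
#' @export
segmentation_mask <- function(mask, voi, spacing_mm, method = "unknown") {
  mask <- mask > 0
  structure(list(mask = mask, voi = voi, spacing_mm = spacing_mm,
                 method = method, failed = !any(mask)),
            class = "dce_mask")
}

#' @export
print.dce_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<dce_mask> %s: %dx%dx%d, %d voxels%s\n", x$method,
              d[1], d[2], d[3], sum(x$mask), if (x$failed) " [FAILED: empty]" else ""))
  invisible(x)
}

# Crop a full-volume array to the VOI grid.
crop_to_voi <- function(arr, voi) {
  arr[voi$row_range[1]:voi$row_range[2],
      voi$col_range[1]:voi$col_range[2],
      voi$first_slice:voi$last_slice, drop = FALSE]
}

# Truth mask of a case restricted to its VOI grid, as a dce_mask.
truth_mask_voi <- function(case) {
  segmentation_mask(crop_to_voi(case$truth_mask, case$voi), case$voi,
                    case$spacing_mm, method = "truth")
}

#' Plot the center subtraction slice of a case with the truth outline
#'
#' @param x a `dce_case`.
#' @param timepoint postcontrast subtraction index shown.
#' @param ... passed to [graphics::image()].
#' @export
plot.dce_case <- function(x, timepoint = 2L, ...) {
  k <- center_slice_index(x$voi)
  sub <- subtraction_image(x, timepoint)[, , k]
  graphics::image(t(sub)[, rev(seq_len(nrow(sub)))], col = grDevices::gray.colors(64),
                  axes = FALSE, asp = nrow(sub) / ncol(sub),
                  main = sprintf("%s (%s %s, post %d)", x$case_id,
                                 x$spec$pathology, x$spec$enhancement_type,
                                 timepoint), ...)
  msk <- x$truth_mask[, , k]
  if (any(msk))
    graphics::contour(t(msk)[, rev(seq_len(nrow(msk)))], levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = "red")
  invisible(x)
}
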