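# Segmentation agreement metrics: Dice similarity coefficient, slicewise
# Hausdorff distance with a per-lesion median, center-slice metrics and the
# effective diameter, plus the failed-segmentation policy (failed lesions
# score DSC 0 and are excluded from Hausdorff statistics).

as_mask_array <- function(x) {
  if (inherits(x, "dce_mask")) x$mask else x > 0
}

#' Dice similarity coefficient
#'
#' 2|A n B| / (|A| + |B|). Two empty masks agree perfectly by convention
#' (DSC 1); an empty versus non-empty mask scores 0.
#'
#' @param a,b binary arrays of identical shape (or `dce_mask` objects).
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b)))
    stop_dceseg("mask shapes differ", "dceseg_integrity_error")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# 4-connectivity boundary pixels of a 2D mask (pixels with a background or
# out-of-image 4-neighbour), as an n x 2 index matrix.
boundary_pixels <- function(mask2d) {
  m <- mask2d > 0
  if (!any(m)) return(matrix(integer(0), 0, 2))
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE] &
    pad[1:d[1], 2:(d[2] + 1L), drop = FALSE] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), drop = FALSE] &
    pad[2:(d[1] + 1L), 1:d[2], drop = FALSE] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), drop = FALSE]
  which(m & !core, arr.ind = TRUE)
}

#' Slicewise Hausdorff distance in mm
#'
#' Symmetric Hausdorff distance max(h(A,B), h(B,A)) with
#' h(A,B) = max_a min_b ||a - b||, computed over 4-connectivity boundary
#' pixels with anisotropic in-plane spacing. Exactly one empty mask gives
#' `NA` (undefined); two empty masks give 0.
#'
#' @param a,b binary 2D masks of identical shape.
#' @param spacing_mm in-plane spacing `c(row, col)` in mm.
#' @return distance in mm, or `NA_real_` when undefined.
#' @export
hausdorff_slice <- function(a, b, spacing_mm = c(1, 1)) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b)))
    stop_dceseg("mask shapes differ", "dceseg_integrity_error")
  ea <- !any(a); eb <- !any(b)
  if (ea && eb) return(0)
  if (ea || eb) return(NA_real_)
  pa <- boundary_pixels(a); pb <- boundary_pixels(b)
  dr <- outer(pa[, 1], pb[, 1], `-`) * spacing_mm[1]
  dc <- outer(pa[, 2], pb[, 2], `-`) * spacing_mm[2]
  dmat <- sqrt(dr^2 + dc^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

#' Per-lesion median of slicewise Hausdorff distances
#'
#' Hausdorff distances are computed for each slice on which both masks are
#' non-empty; the lesion-level summary is their median. If no slice has both
#' masks non-empty (e.g. a failed segmentation) the result is `NA` and the
#' lesion is excluded from Hausdorff statistics.
#'
#' @param pred,ref binary 3D masks on the same grid.
#' @param spacing_mm named `c(row, col, slice)` spacing.
#' @return median HD in mm, or `NA_real_`.
#' @export
lesion_median_hd <- function(pred, ref, spacing_mm) {
  pred <- as_mask_array(pred); ref <- as_mask_array(ref)
  if (!identical(dim(pred), dim(ref)))
    stop_dceseg("mask grids differ", "dceseg_integrity_error")
  ip <- c(spacing_mm[["row"]], spacing_mm[["col"]])
  hds <- vapply(seq_len(dim(pred)[3]), function(k) {
    pk <- pred[, , k]; rk <- ref[, , k]
    if (any(pk) && any(rk)) hausdorff_slice(pk, rk, ip) else NA_real_
  }, numeric(1))
  hds <- hds[!is.na(hds)]
  if (!length(hds)) return(NA_real_)
  stats::median(hds)
}

#' Center slice index of a VOI
#'
#' `floor((first_slice + last_slice) / 2)` — the middle slice, rounding to
#' the lower of the two central slices for an even slice count.
#'
#' @param voi a [lesion_voi()].
#' @export
center_slice_index <- function(voi) {
  as.integer(floor((voi$first_slice + voi$last_slice) / 2))
}

#' Effective diameter of a center-slice mask
#'
#' 2*sqrt(A/pi) with A the lesion area (pixel count times pixel area in mm^2)
#' in the center slice.
#'
#' @param center_slice_mask binary 2D mask.
#' @param spacing_mm in-plane spacing `c(row, col)` in mm.
#' @return diameter in mm.
#' @export
effective_diameter <- function(center_slice_mask, spacing_mm = c(1, 1)) {
  m <- as_mask_array(center_slice_mask)
  a <- sum(m) * unname(spacing_mm[1] * spacing_mm[2])
  if (a == 0) stop_dceseg("center slice is empty", "dceseg_value_error")
  2 * sqrt(a / pi)
}

#' Evaluate one lesion's segmentation against a reference
#'
#' Produces one metric record: volume DSC, per-lesion median slicewise HD,
#' center-slice DSC and HD, and the failed flag. A failed (empty) prediction
#' contributes DSC = 0 with undefined HD.
#'
#' @param pred,ref `dce_mask` objects (or binary arrays) on the same VOI grid.
#' @param voi the VOI (used for the center-slice convention); defaults to
#'   `pred$voi`.
#' @param spacing_mm named spacing; defaults to `pred$spacing_mm`.
#' @param lesion_id,method,reference,timepoint,strata record labels; `strata`
#'   is a named list/row with pathology, enhancement_type, size_bin.
#' @return one-row data.frame (a MetricRecord).
#' @export
evaluate_lesion <- function(pred, ref, voi = NULL, spacing_mm = NULL,
                            lesion_id = "lesion", method = "method",
                            reference = "reference", timepoint = NA_integer_,
                            strata = NULL) {
  if (inherits(pred, "dce_mask")) {
    voi <- voi %||% pred$voi
    spacing_mm <- spacing_mm %||% pred$spacing_mm
  }
  p <- as_mask_array(pred); r <- as_mask_array(ref)
  if (!identical(dim(p), dim(r)))
    stop_dceseg("prediction and reference grids differ", "dceseg_integrity_error")
  failed <- !any(p)
  dsc <- dice(p, r)
  mhd <- if (failed) NA_real_ else lesion_median_hd(p, r, spacing_mm)
  # center slice in VOI-grid coordinates
  k <- center_slice_index(voi) - voi$first_slice + 1L
  k <- max(1L, min(dim(p)[3], k))
  ip <- c(spacing_mm[["row"]], spacing_mm[["col"]])
  cd <- dice(p[, , k], r[, , k])
  chd <- if (any(p[, , k]) && any(r[, , k])) hausdorff_slice(p[, , k], r[, , k], ip) else NA_real_
  data.frame(lesion_id = lesion_id, method = method, reference = reference,
             timepoint = timepoint,
             dsc = if (failed) 0 else dsc,
             median_hd_mm = mhd,
             center_dsc = if (failed) 0 else cd,
             center_hd_mm = chd,
             failed = failed,
             pathology = strata$pathology %||% NA_character_,
             enhancement_type = strata$enhancement_type %||% NA_character_,
             size_bin = strata$size_bin %||% NA_character_,
             stringsAsFactors = FALSE)
}
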