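# NIfTI readers/writers, manifest handling and run configuration.

#' Clinical size bin of an effective diameter
#'
#' Bins partition the positive reals with half-open edges:
#' (0,5), [5,10), [10,15), [15,20), [20, Inf), labelled `"<5"`, `"5 to 9"`,
#' `"10 to 14"`, `"15 to 19"`, `">20"`.
#'
#' @param effective_diameter_mm diameter(s) in mm, > 0.
#' @return character vector of bin labels.
#' @export
size_bin <- function(effective_diameter_mm) {
  if (any(effective_diameter_mm <= 0))
    stop_dceseg("effective diameter must be > 0", "dceseg_value_error")
  labels <- c("<5", "5 to 9", "10 to 14", "15 to 19", ">20")
  idx <- findInterval(effective_diameter_mm, c(0, 5, 10, 15, 20))
  labels[idx]
}

#' Write a DCE case to NIfTI files
#'
#' The 4D series and the binary truth mask are written as `.nii.gz` with the
#' voxel spacing in the header; VOI and labels travel in the cohort manifest.
#'
#' @param case a `dce_case`.
#' @param dir output directory (created if needed).
#' @return list with elements `series` and `truth` (file paths).
#' @export
write_case <- function(case, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_dceseg("cannot create output directory", "dceseg_io_error")
  sp <- unname(case$spacing_mm[c("row", "col", "slice")])
  series_path <- file.path(dir, paste0(case$case_id, "_series.nii.gz"))
  truth_path <- file.path(dir, paste0(case$case_id, "_truth.nii.gz"))
  img <- RNifti::asNifti(case$series)
  RNifti::pixdim(img) <- c(sp, 1)
  RNifti::writeNifti(img, series_path, datatype = "float")
  msk <- RNifti::asNifti(array(as.integer(case$truth_mask), dim(case$truth_mask)))
  RNifti::pixdim(msk) <- sp
  RNifti::writeNifti(msk, truth_path, datatype = "uint8")
  list(series = series_path, truth = truth_path)
}

#' Read a DCE case back from NIfTI files and a manifest row
#'
#' @param manifest_row one row of a cohort manifest (with paths, VOI columns,
#'   labels and spacing).
#' @return a `dce_case`.
#' @export
read_case <- function(manifest_row) {
  series <- RNifti::readNifti(manifest_row$series_path)
  truth <- RNifti::readNifti(manifest_row$truth_path)
  sd <- dim(series); td <- dim(truth)
  if (length(sd) != 4L || !all(sd[1:3] == td))
    stop_dceseg("series and mask shapes are inconsistent", "dceseg_integrity_error")
  sp_series <- RNifti::pixdim(series)[1:3]
  sp_mask <- RNifti::pixdim(truth)[1:3]
  if (any(abs(sp_series - sp_mask) > 1e-4))
    stop_dceseg("series and mask spacing are inconsistent", "dceseg_integrity_error")
  spec <- lesion_spec(manifest_row$enhancement_type, manifest_row$pathology,
                      manifest_row$effective_diameter_mm,
                      kinetic = kinetic_class(manifest_row$kinetic_class),
                      seed = manifest_row$seed)
  structure(list(series = array(as.numeric(series), sd),
                 spacing_mm = c(row = sp_series[1], col = sp_series[2], slice = sp_series[3]),
                 timepoints_s = NULL,
                 truth_mask = array(truth > 0, td),
                 voi = voi_from_columns(manifest_row),
                 spec = spec,
                 case_id = manifest_row$case_id),
            class = "dce_case")
}

#' Read a cohort manifest
#' @param path CSV manifest path.
#' @return data.frame; case_id uniqueness and size-bin consistency are checked.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(man$case_id))
    stop_dceseg("duplicate case_id in manifest", "dceseg_integrity_error")
  if (!all(man$size_bin == size_bin(man$effective_diameter_mm)))
    stop_dceseg("size_bin column inconsistent with effective_diameter_mm",
                "dceseg_integrity_error")
  man
}

#' Run configuration
#'
#' Bundles the tunables of a full experiment run. Defaults are the package's
#' desk-scale study conditions; `unet2d`/`unet3d` are passed to
#' [unet_config()].
#'
#' @param folds number of cross-validation folds (>= 2).
#' @param threshold_grid candidate probability thresholds, all in (0, 1).
#' @param seed master seed.
#' @param unet2d,unet3d lists of U-Net hyperparameter overrides.
#' @param out_dir output directory (or `NULL` for in-memory runs).
#' @export
run_config <- function(folds = 5L, threshold_grid = seq(0.14, 0.30, by = 0.01),
                       seed = 1L, unet2d = list(), unet3d = list(),
                       out_dir = NULL) {
  if (folds < 2L) stop_dceseg("fold count must be >= 2", "dceseg_value_error")
  if (any(threshold_grid <= 0 | threshold_grid >= 1))
    stop_dceseg("threshold grid must lie in (0, 1)", "dceseg_value_error")
  structure(list(folds = as.integer(folds), threshold_grid = threshold_grid,
                 seed = as.integer(seed), unet2d = unet2d, unet3d = unet3d,
                 out_dir = out_dir),
            class = "dce_run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

# Stable content hash used for run provenance logging.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
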