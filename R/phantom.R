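# Synthetic DCE-MRI lesion phantoms.
#
# Volumes are arrays indexed [row, col, slice] (1-based, inclusive ranges);
# a 4D series adds time as the 4th dimension with index 1 = precontrast.
# Spacing is a named vector c(row, col, slice) in mm.

#' Construct a lesion specification
#'
#' @param enhancement_type `"mass"` (compact, space-occupying enhancement),
#'   `"nonmass"` (diffuse, scattered enhancement) or `"unknown"` (lesions in
#'   the source cohorts whose radiology report carried neither label; they
#'   are generated with mass-like morphology).
#' @param pathology `"benign"` or `"malignant"`.
#' @param effective_diameter_mm target effective diameter 2*sqrt(A/pi) of the
#'   lesion's center slice, in mm (> 0).
#' @param kinetic a [kinetic_class()]; defaults to persistent for benign and
#'   washout for malignant lesions.
#' @param seed integer seed making the generated case reproducible.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(enhancement_type = c("mass", "nonmass", "unknown"),
                        pathology = c("malignant", "benign"),
                        effective_diameter_mm = 10,
                        kinetic = NULL, seed = 1L) {
  enhancement_type <- match.arg(enhancement_type)
  pathology <- match.arg(pathology)
  if (effective_diameter_mm <= 0)
    stop_dceseg("effective_diameter_mm must be > 0", "dceseg_value_error")
  structure(list(enhancement_type = enhancement_type, pathology = pathology,
                 effective_diameter_mm = as.numeric(unname(effective_diameter_mm)),
                 kinetic = kinetic %||% default_kinetic_for(pathology),
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Default acquisition protocol for phantom generation
#'
#' Defaults follow a routine breast DCE protocol: one precontrast plus three
#' postcontrast acquisitions at a 75 s temporal resolution, in-plane spacing
#' drawn from 0.5-1.0 mm and slice thickness from 1-3.5 mm (fixed per case),
#' additive Gaussian noise with sd equal to 5% of the baseline signal, and
#' smooth background parenchymal enhancement whose amplitude is 20% of the
#' lesion peak enhancement.
#'
#' @param timepoints_s acquisition times (s), starting at 0.
#' @param spacing_mm named numeric `c(row, col, slice)` in mm, or `NULL` to
#'   draw per-case spacing from the protocol ranges.
#' @param baseline mean precontrast signal intensity (arbitrary units).
#' @param noise_sd_frac noise sd as a fraction of `baseline`.
#' @param background_frac background parenchymal enhancement amplitude as a
#'   fraction of the lesion's peak enhancement.
#' @param voi_margin_inplane,voi_margin_slices margin (voxels / slices) of the
#'   operator bounding box around the lesion support.
#' @return list of class `dce_protocol`.
#' @export
dce_protocol <- function(timepoints_s = c(0, 75, 150, 225),
                         spacing_mm = NULL,
                         baseline = 200,
                         noise_sd_frac = 0.05,
                         background_frac = 0.2,
                         voi_margin_inplane = 4L,
                         voi_margin_slices = 1L) {
  if (length(timepoints_s) < 3L || timepoints_s[1] != 0 || any(diff(timepoints_s) <= 0))
    stop_dceseg("protocol needs >= 3 strictly increasing timepoints starting at 0",
                "dceseg_invalid_protocol")
  if (voi_margin_inplane < 1L || voi_margin_slices < 1L)
    stop_dceseg("VOI margins must be >= 1", "dceseg_value_error")
  structure(list(timepoints_s = timepoints_s, spacing_mm = spacing_mm,
                 baseline = baseline, noise_sd_frac = noise_sd_frac,
                 background_frac = background_frac,
                 voi_margin_inplane = as.integer(voi_margin_inplane),
                 voi_margin_slices = as.integer(voi_margin_slices)),
            class = "dce_protocol")
}

#' Operator bounding-box VOI
#'
#' Rectangular in-plane box plus first/last slice indices, all 1-based and
#' inclusive, mimicking the operator input of clinical FCM workstations.
#'
#' @param row_range,col_range inclusive `c(first, last)` index pairs.
#' @param first_slice,last_slice inclusive slice indices.
#' @export
lesion_voi <- function(row_range, col_range, first_slice, last_slice) {
  if (first_slice > last_slice || row_range[1] > row_range[2] || col_range[1] > col_range[2])
    stop_dceseg("VOI ranges must be non-empty", "dceseg_geometry_error")
  structure(list(row_range = as.integer(row_range), col_range = as.integer(col_range),
                 first_slice = as.integer(first_slice), last_slice = as.integer(last_slice)),
            class = "lesion_voi")
}

voi_from_mask <- function(mask, margin_inplane, margin_slices) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop_dceseg("mask is empty", "dceseg_geometry_error")
  d <- dim(mask)
  lesion_voi(
    row_range = c(max(1L, min(idx[, 1]) - margin_inplane), min(d[1], max(idx[, 1]) + margin_inplane)),
    col_range = c(max(1L, min(idx[, 2]) - margin_inplane), min(d[2], max(idx[, 2]) + margin_inplane)),
    first_slice = max(1L, min(idx[, 3]) - margin_slices),
    last_slice = min(d[3], max(idx[, 3]) + margin_slices))
}

# center-slice pixel area -> effective diameter, in voxel units of a mask
measure_effective_diameter <- function(mask, slice, spacing_mm) {
  a <- sum(mask[, , slice] > 0) * spacing_mm[["row"]] * spacing_mm[["col"]]
  2 * sqrt(a / pi)
}

center_of_support <- function(mask) {
  ks <- which(apply(mask > 0, 3, any))
  floor((min(ks) + max(ks)) / 2)
}

# Ellipsoid indicator on the voxel grid, axes in mm.
ellipsoid_mask <- function(dims, center, radii_mm, spacing_mm) {
  rr <- (seq_len(dims[1]) - center[1]) * spacing_mm[["row"]]
  cc <- (seq_len(dims[2]) - center[2]) * spacing_mm[["col"]]
  ss <- (seq_len(dims[3]) - center[3]) * spacing_mm[["slice"]]
  q <- outer(outer((rr / radii_mm[1])^2, (cc / radii_mm[2])^2, `+`),
             (ss / radii_mm[3])^2, `+`)
  q <= 1
}

#' Generate a binary 3D lesion shape
#'
#' Mass lesions are single smoothed ellipsoidal blobs (Gaussian-smoothed
#' indicator thresholded at half-max); nonmass lesions are unions of several
#' small blobs that stay disconnected in the center slice, emulating diffuse
#' scattered enhancement. In both cases the in-plane extent is calibrated so
#' the center-slice effective diameter 2*sqrt(A/pi) matches
#' `spec$effective_diameter_mm` to within one in-plane voxel.
#'
#' @param spec a [lesion_spec()].
#' @param spacing_mm named `c(row, col, slice)` spacing in mm.
#' @param dims volume dimensions `(rows, cols, slices)`.
#' @param center voxel coordinate of the lesion center (defaults to the
#'   volume center).
#' @return logical array of dimension `dims`.
#' @export
generate_lesion_shape <- function(spec, spacing_mm, dims, center = NULL) {
  d_mm <- spec$effective_diameter_mm
  inplane <- c(spacing_mm[["row"]], spacing_mm[["col"]])
  extent_mm <- c(dims[1] * inplane[1], dims[2] * inplane[2])
  if (any(d_mm * 1.2 > extent_mm))
    stop_dceseg("requested diameter does not fit the volume extent", "dceseg_geometry_error")
  center <- center %||% (dims + 1) / 2
  with_seed((spec$seed %% 268435456L) * 7L + 11L, {
    if (spec$enhancement_type == "nonmass") {
      nonmass_shape(d_mm, spacing_mm, dims, center)
    } else {
      mass_shape(d_mm, spacing_mm, dims, center)
    }
  })
}

mass_shape <- function(d_mm, spacing_mm, dims, center) {
  q <- exp(stats::runif(1, -0.18, 0.18))      # mild in-plane anisotropy, area-neutral
  jitter <- stats::runif(3, -0.3, 0.3)
  r_in <- d_mm / 2
  r_ax <- max(d_mm / 2, 1.2 * spacing_mm[["slice"]])   # >= 3 slices of support
  scale <- 1
  mask <- NULL
  for (it in 1:5) {
    radii <- c(r_in * scale * q, r_in * scale / q, r_ax)
    ind <- ellipsoid_mask(dims, center + jitter, radii, spacing_mm)
    sm <- smooth_gauss3(ind * 1, c(0.7, 0.7, 0.3))
    mask <- sm > 0.5 * max(sm)
    if (!any(mask)) mask <- ind
    realized <- measure_effective_diameter(mask, center_of_support(mask), spacing_mm)
    if (abs(realized - d_mm) <= 0.5 * min(spacing_mm[c("row", "col")])) break
    scale <- scale * d_mm / realized
  }
  mask
}

nonmass_shape <- function(d_mm, spacing_mm, dims, center) {
  target_area <- pi * (d_mm / 2)^2
  for (attempt in 1:25) {
    k <- sample(3:8, 1)
    r_b <- max(d_mm / (2 * sqrt(k)), 0.9 * max(spacing_mm[c("row", "col")]))
    # scatter blob centers inside a diffuse envelope, all crossing the center slice
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- d_mm * stats::runif(k, 0.3, 0.7)
    ctr <- cbind(center[1] + rad * cos(ang) / spacing_mm[["row"]],
                 center[2] + rad * sin(ang) / spacing_mm[["col"]],
                 center[3] + stats::runif(k, -0.4, 0.4))
    scale <- 1
    mask <- NULL
    for (it in 1:5) {
      mask <- array(FALSE, dims)
      for (b in seq_len(k)) {
        rb <- r_b * scale
        mask <- mask | ellipsoid_mask(dims, ctr[b, ],
                                      c(rb, rb, max(rb, 1.1 * spacing_mm[["slice"]])),
                                      spacing_mm)
      }
      if (!any(mask)) break
      cs <- center_of_support(mask)
      realized <- measure_effective_diameter(mask, cs, spacing_mm)
      if (realized > 0 && abs(realized - d_mm) <= 0.5 * min(spacing_mm[c("row", "col")])) break
      if (realized > 0) scale <- scale * d_mm / realized
    }
    if (is.null(mask) || !any(mask)) next
    cs <- center_of_support(mask)
    ncc <- max(label_components(mask[, , cs], connectivity = 4L))
    realized <- measure_effective_diameter(mask, cs, spacing_mm)
    if (ncc >= 2L && abs(realized - d_mm) <= min(spacing_mm[c("row", "col")])) return(mask)
  }
  stop_dceseg("could not place a disconnected nonmass shape in the volume; increase the grid",
              "dceseg_geometry_error")
}

#' Generate one synthetic DCE-MRI lesion case
#'
#' Builds a 4D series in which truth-mask voxels follow
#' `baseline * (1 + e(t))` for the lesion's kinetic curve `e`, background
#' tissue carries a weaker spatially smooth parenchymal enhancement, and
#' every voxel/timepoint receives additive Gaussian noise. The operator VOI
#' is the truth-mask bounding box plus the protocol margins. The output is a
#' pure function of `(spec, protocol, seed)`.
#'
#' @param spec a [lesion_spec()].
#' @param protocol a [dce_protocol()].
#' @param seed integer; defaults to `spec$seed`.
#' @param case_id identifier string.
#' @return object of class `dce_case` with fields `series` (4D array
#'   row x col x slice x time), `spacing_mm`, `timepoints_s`, `truth_mask`,
#'   `voi`, `spec`, `case_id`.
#' @export
generate_dce_case <- function(spec, protocol = dce_protocol(), seed = spec$seed,
                              case_id = sprintf("case_%06d", seed)) {
  stopifnot(inherits(spec, "lesion_spec"), inherits(protocol, "dce_protocol"))
  with_seed(seed, {
    spacing <- protocol$spacing_mm
    if (is.null(spacing)) {
      ip <- stats::runif(1, 0.5, 1.0)
      spacing <- c(row = ip, col = ip, slice = stats::runif(1, 1.0, 3.5))
    }
    d_mm <- spec$effective_diameter_mm
    m_ip <- protocol$voi_margin_inplane
    m_sl <- protocol$voi_margin_slices
    pad_ip <- 6L; pad_sl <- 2L
    # nonmass lesions scatter blobs over a wider envelope than a compact mass
    f_ext <- if (spec$enhancement_type == "nonmass") 2.1 else 1.4
    n_ip_r <- ceiling(f_ext * d_mm / spacing[["row"]]) + 2L * (m_ip + pad_ip)
    n_ip_c <- ceiling(f_ext * d_mm / spacing[["col"]]) + 2L * (m_ip + pad_ip)
    n_sl <- ceiling(d_mm / spacing[["slice"]]) + 2L * (m_sl + pad_sl) + 3L
    dims <- c(n_ip_r, n_ip_c, n_sl)

    mask <- generate_lesion_shape(spec, spacing, dims)
    voi <- voi_from_mask(mask, m_ip, m_sl)
    curve <- enhancement_curve(spec$kinetic, protocol$timepoints_s)
    nt <- length(curve)

    # smooth background parenchymal enhancement field in [0, 1]
    bg_field <- smooth_gauss3(array(stats::runif(prod(dims)), dims), c(3, 3, 1.5))
    rng <- range(bg_field)
    bg_field <- (bg_field - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    bg_amp <- protocol$background_frac * spec$kinetic$peak_enhancement
    ramp <- protocol$timepoints_s / max(protocol$timepoints_s)

    series <- array(0, c(dims, nt))
    b <- protocol$baseline
    for (t in seq_len(nt)) {
      vol <- array(b, dims)
      vol[!mask] <- b * (1 + bg_amp * ramp[t] * bg_field[!mask])
      vol[mask] <- b * (1 + curve[t])
      if (protocol$noise_sd_frac > 0)
        vol <- vol + stats::rnorm(prod(dims), sd = protocol$noise_sd_frac * b)
      series[, , , t] <- vol
    }
    structure(list(series = series, spacing_mm = spacing,
                   timepoints_s = protocol$timepoints_s,
                   truth_mask = mask, voi = voi, spec = spec, case_id = case_id),
              class = "dce_case")
  })
}

#' @export
print.dce_case <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("<dce_case> %s: %s %s lesion, %.1f mm, %dx%dx%d voxels x %d timepoints\n",
              x$case_id, x$spec$pathology, x$spec$enhancement_type,
              x$spec$effective_diameter_mm, d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.2f x %.2f x %.2f mm; VOI rows %d-%d cols %d-%d slices %d-%d\n",
              x$spacing_mm[["row"]], x$spacing_mm[["col"]], x$spacing_mm[["slice"]],
              x$voi$row_range[1], x$voi$row_range[2], x$voi$col_range[1],
              x$voi$col_range[2], x$voi$first_slice, x$voi$last_slice))
  invisible(x)
}

#' Postcontrast subtraction image
#'
#' @param case a `dce_case`.
#' @param post_index postcontrast acquisition number (1 = first postcontrast).
#' @return 3D array `series[,,,1 + post_index] - series[,,,1]`.
#' @export
subtraction_image <- function(case, post_index) {
  nt <- dim(case$series)[4]
  if (post_index < 1 || post_index > nt - 1)
    stop_dceseg("post_index must be in 1..(timepoints - 1)", "dceseg_index_error")
  out <- case$series[, , , 1 + post_index, drop = FALSE] -
    case$series[, , , 1, drop = FALSE]
  dim(out) <- dim(case$series)[1:3]
  out
}

# Table-1-style default composition of the cohort (proportions of the
# 994-lesion clinical dataset this generator emulates).
default_composition <- function() {
  data.frame(
    enhancement_type = rep(c("mass", "nonmass", "unknown"), each = 2),
    pathology = rep(c("benign", "malignant"), 3),
    prop = c(170, 517, 49, 175, 51, 32) / 994,
    stringsAsFactors = FALSE)
}

# Size-bin sampling distribution (counts of the emulated dataset) and
# within-bin uniform diameter ranges.
default_size_distribution <- function() {
  list(bins = c("<5", "5 to 9", "10 to 14", "15 to 19", ">20"),
       prob = c(64, 344, 252, 125, 209) / 994,
       ranges = list(`<5` = c(3.2, 5), `5 to 9` = c(5, 10), `10 to 14` = c(10, 15),
                     `15 to 19` = c(15, 20), `>20` = c(20, 26)))
}

largest_remainder <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Sample a cohort composition table
#'
#' Allocates `n` lesions to the enhancement-type x pathology strata by
#' largest-remainder rounding of the composition proportions (realized
#' counts within one case of `n * prop` per stratum) and draws effective
#' diameters from the five clinical size bins. This is the manifest-level
#' cohort draw; [generate_cohort()] turns each row into an image phantom.
#'
#' @param n number of lesions (>= 1).
#' @param composition data.frame with columns `enhancement_type`, `pathology`,
#'   `prop` summing to 1; defaults to the clinical composition table.
#' @param seed cohort seed.
#' @param size_distribution optional override of the size-bin sampling.
#' @return data.frame with case_id, pathology, enhancement_type,
#'   effective_diameter_mm, size_bin, kinetic_class and the per-case seed.
#' @export
sample_cohort_table <- function(n, composition = default_composition(),
                                seed = 1L,
                                size_distribution = default_size_distribution()) {
  if (n < 1) stop_dceseg("n must be >= 1", "dceseg_value_error")
  if (abs(sum(composition$prop) - 1) > 1e-8)
    stop_dceseg("composition proportions must sum to 1", "dceseg_value_error")
  counts <- largest_remainder(n, composition$prop)
  rows <- composition[rep(seq_len(nrow(composition)), counts),
                      c("enhancement_type", "pathology")]
  rownames(rows) <- NULL
  sd_dist <- size_distribution
  with_seed(seed, {
    bins <- sample(sd_dist$bins, n, replace = TRUE, prob = sd_dist$prob)
    diam <- unname(vapply(bins, function(b)
      stats::runif(1, sd_dist$ranges[[b]][1], sd_dist$ranges[[b]][2]), 0))
    case_seeds <- sample.int(2^28, n)  # distinct per-case seeds, headroom for derivation
    data.frame(case_id = sprintf("case_%04d", seq_len(n)),
               pathology = rows$pathology,
               enhancement_type = rows$enhancement_type,
               effective_diameter_mm = diam,
               size_bin = size_bin(diam),
               kinetic_class = vapply(rows$pathology, function(p)
                 default_kinetic_for(p)$name, ""),
               seed = case_seeds,
               stringsAsFactors = FALSE)
  })
}

#' Generate a cohort of synthetic lesion cases
#'
#' Draws the cohort table with [sample_cohort_table()] and generates each
#' case's 4D phantom. With `out_dir` set, each case's series and truth mask
#' are written as NIfTI files and the manifest as CSV.
#'
#' @inheritParams sample_cohort_table
#' @param protocol a [dce_protocol()].
#' @param out_dir optional output directory; when `NULL` cases stay in memory.
#' @return list with `manifest` (data.frame) and `cases` (list of `dce_case`,
#'   or `NULL` when written to disk).
#' @export
generate_cohort <- function(n, composition = default_composition(),
                            protocol = dce_protocol(), seed = 1L,
                            out_dir = NULL,
                            size_distribution = default_size_distribution()) {
  tab <- sample_cohort_table(n, composition, seed, size_distribution)
  specs <- lapply(seq_len(n), function(i)
    lesion_spec(tab$enhancement_type[i], tab$pathology[i],
                tab$effective_diameter_mm[i], seed = tab$seed[i]))

  cases <- vector("list", n)
  man <- vector("list", n)
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_dceseg("cannot create output directory", "dceseg_io_error")
  for (i in seq_len(n)) {
    id <- sprintf("case_%04d", i)
    case <- generate_dce_case(specs[[i]], protocol, case_id = id)
    row <- data.frame(
      case_id = id,
      pathology = case$spec$pathology,
      enhancement_type = case$spec$enhancement_type,
      effective_diameter_mm = case$spec$effective_diameter_mm,
      size_bin = size_bin(case$spec$effective_diameter_mm),
      kinetic_class = case$spec$kinetic$name,
      seed = case$spec$seed,
      series_path = NA_character_, truth_path = NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      paths <- write_case(case, out_dir)
      row$series_path <- paths$series
      row$truth_path <- paths$truth
    } else {
      cases[[i]] <- case
    }
    man[[i]] <- cbind(row, voi_to_columns(case$voi),
                      data.frame(spacing_row = case$spacing_mm[["row"]],
                                 spacing_col = case$spacing_mm[["col"]],
                                 spacing_slice = case$spacing_mm[["slice"]]))
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    cases <- NULL
  }
  list(manifest = manifest, cases = cases)
}

voi_to_columns <- function(voi) {
  data.frame(voi_row1 = voi$row_range[1], voi_row2 = voi$row_range[2],
             voi_col1 = voi$col_range[1], voi_col2 = voi$col_range[2],
             voi_slice1 = voi$first_slice, voi_slice2 = voi$last_slice)
}

voi_from_columns <- function(row) {
  lesion_voi(c(row$voi_row1, row$voi_row2), c(row$voi_col1, row$voi_col2),
             row$voi_slice1, row$voi_slice2)
}
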