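# Fuzzy c-means segmentation of contrast uptake.
#
# Each VOI voxel is described by its relative-enhancement vector, one value
# per postcontrast timepoint: (S_t - S_0) / max(S_0, eps). Soft clustering
# of these kinetic features separates enhancing lesion from background
# tissue; the lesion cluster is the one whose centroid carries the highest
# mean enhancement. This is the classic clinical contrast-uptake
# segmentation used as a surrogate reference standard for training and
# evaluating the U-Net arms.

#' Extract per-voxel enhancement features inside a VOI
#'
#' @param case a `dce_case`.
#' @param voi a [lesion_voi()]; must lie within the volume.
#' @param eps guard for the precontrast denominator (intensity units).
#' @return list with `features` (matrix, VOI voxels x postcontrast
#'   timepoints, in column-major VOI grid order) and `dims` (VOI grid
#'   dimensions).
#' @export
extract_features <- function(case, voi = case$voi, eps = 1) {
  d <- dim(case$series)
  nt <- d[4]
  if (nt < 3L)
    stop_dceseg("need >= 2 postcontrast timepoints", "dceseg_invalid_protocol")
  if (voi$row_range[1] < 1 || voi$col_range[1] < 1 || voi$first_slice < 1 ||
      voi$row_range[2] > d[1] || voi$col_range[2] > d[2] || voi$last_slice > d[3])
    stop_dceseg("VOI out of volume bounds", "dceseg_geometry_error")
  rows <- voi$row_range[1]:voi$row_range[2]
  cols <- voi$col_range[1]:voi$col_range[2]
  slices <- voi$first_slice:voi$last_slice
  s0 <- as.vector(case$series[rows, cols, slices, 1])
  denom <- pmax(s0, eps)
  feats <- vapply(2:nt, function(t)
    (as.vector(case$series[rows, cols, slices, t]) - s0) / denom,
    numeric(length(s0)))
  list(features = feats, dims = c(length(rows), length(cols), length(slices)))
}

# k-means++-style centroid seeding on the feature rows.
seed_centroids <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  centers <- x[idx, , drop = FALSE]
  while (nrow(centers) < c) {
    d2 <- apply(centers, 1, function(v) rowSums((x - rep(v, each = n))^2))
    mind <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    if (all(mind <= 0)) {
      centers <- rbind(centers, x[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, x[sample.int(n, 1, prob = mind), , drop = FALSE])
    }
  }
  centers
}

#' Fuzzy c-means alternating updates
#'
#' Minimizes J = sum_k sum_i u_ik^m ||x_k - v_i||^2 by the standard
#' alternating membership/centroid updates until the maximum membership
#' change drops below `tol` or `max_iter` is reached.
#'
#' @param features numeric matrix (observations x features).
#' @param c number of clusters (default 2: lesion vs background).
#' @param m fuzziness exponent (> 1, default 2).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @param seed seed for centroid initialization.
#' @param v_init optional explicit initial centroid matrix (c x features),
#'   bypassing the seeded initialization.
#' @return object of class `dce_fcm`: memberships `u` (observations x c,
#'   rows summing to 1), centroids `v` (c x features), objective trace
#'   `J` (non-increasing), and `iterations`.
#' @export
fcm_iterate <- function(features, c = 2L, m = 2, tol = 1e-5, max_iter = 100L,
                        seed = 1L, v_init = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (m <= 1) stop_dceseg("fuzziness m must be > 1", "dceseg_value_error")
  if (nrow(unique(x)) < c)
    stop_dceseg("need at least c distinct feature vectors", "dceseg_degenerate_data")
  v <- if (is.null(v_init)) with_seed(seed, seed_centroids(x, c)) else as.matrix(v_init)
  u <- matrix(1 / c, n, c)
  Jtrace <- numeric(0)
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(i)
      rowSums((x - rep(v[i, ], each = n))^2), numeric(n))
    d2 <- pmax(d2, .Machine$double.eps)
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    um <- u_new^m
    Jtrace <- c(Jtrace, sum(um * d2))
    v <- t(um) %*% x / colSums(um)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  structure(list(u = u, v = v, m = m, J = Jtrace, iterations = length(Jtrace)),
            class = "dce_fcm")
}

#' @export
print.dce_fcm <- function(x, ...) {
  cat(sprintf("<dce_fcm> %d clusters, %d observations, %d iterations, final J = %.4g\n",
              ncol(x$u), nrow(x$u), x$iterations, utils::tail(x$J, 1)))
  invisible(x)
}

#' Segment a lesion by fuzzy c-means inside the operator VOI
#'
#' Clusters the VOI voxels' enhancement features with [fcm_iterate()], takes
#' the cluster with the highest mean-enhancement centroid as lesion, assigns
#' voxels with lesion membership > 0.5, keeps the largest 3D connected
#' component (26-connectivity) and fills in-plane holes. An empty result is
#' allowed and flagged `failed`.
#'
#' @param case a `dce_case`.
#' @param voi VOI (defaults to the case's operator VOI).
#' @param c,m,tol,max_iter,eps,seed FCM configuration; see [fcm_iterate()]
#'   and [extract_features()].
#' @return a [segmentation_mask()] on the VOI grid (method `"fcm"`).
#' @export
segment_fcm <- function(case, voi = case$voi, c = 2L, m = 2, tol = 1e-5,
                        max_iter = 100L, eps = 1, seed = 1L) {
  fe <- extract_features(case, voi, eps)
  mask <- tryCatch({
    fit <- fcm_iterate(fe$features, c = c, m = m, tol = tol,
                       max_iter = max_iter, seed = seed)
    lesion_cl <- which.max(rowMeans(fit$v))
    assigned <- fit$u[, lesion_cl] > 0.5
    mask <- array(assigned, fe$dims)
    if (any(mask)) fill_holes_inplane(keep_largest_component(mask)) else mask
  }, dceseg_degenerate_data = function(e) array(FALSE, fe$dims))
  segmentation_mask(mask, voi, case$spacing_mm, method = "fcm")
}
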