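# Internal array utilities shared by the phantom generator, the FCM
# postprocessing and the metrics: connected-component labelling, in-plane
# hole filling, separable Gaussian smoothing and bilinear resizing.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dceseg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dceseg_error")))
}

#' Label connected components of a binary array
#'
#' Breadth-first labelling of a logical/0-1 array. 2D arrays use
#' 4-connectivity, 3D arrays 26-connectivity (the conventions used for
#' in-plane boundaries and volumetric lesion objects respectively).
#'
#' @param mask logical or 0/1 array (2D matrix or 3D array).
#' @param connectivity 4 or 8 for 2D; 6 or 26 for 3D.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in discovery order.
#' @keywords internal
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_dceseg("mask must be a 2D or 3D array", "dceseg_geometry_error")
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 4L else 26L
  mask <- mask > 0
  # pad by one voxel on every side so linear-index neighbour offsets never wrap
  pd <- d + 2L
  padded <- array(FALSE, pd)
  if (nd == 2L) padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  else padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask

  deltas <- if (nd == 2L) {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0), , drop = FALSE]
    if (connectivity == 4L) g <- g[abs(g[, 1]) + abs(g[, 2]) == 1L, , drop = FALSE]
    g
  } else {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
    g
  }
  strides <- cumprod(c(1L, pd[-nd]))
  offsets <- as.integer(deltas %*% strides)

  labels <- array(0L, pd)
  todo <- which(padded)
  lab <- 0L
  while (length(todo)) {
    seedv <- todo[labels[todo] == 0L]
    if (!length(seedv)) break
    todo <- seedv
    lab <- lab + 1L
    frontier <- todo[1L]
    labels[frontier] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offsets, `+`)))
      nb <- nb[padded[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  out <- if (nd == 2L) labels[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE]
         else labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  dim(out) <- d
  out
}

# Keep only the largest connected component (26-connectivity for 3D).
keep_largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(mask > 0)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Fill holes of a 2D slice: background components (4-connectivity) not
# connected to the slice border become foreground.
fill_holes_slice <- function(mask2d) {
  d <- dim(mask2d)
  pd <- d + 2L
  padded <- array(TRUE, pd)               # pad ring = background after negation
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- !(mask2d > 0)
  bg <- label_components(padded, connectivity = 4L)
  outside <- bg[1L, 1L]
  inner <- bg[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE]
  filled <- (mask2d > 0) | (inner != outside & inner > 0L)
  dim(filled) <- d
  filled
}

# Fill in-plane holes of every slice of a 3D mask.
fill_holes_inplane <- function(mask3d) {
  out <- mask3d > 0
  for (k in seq_len(dim(mask3d)[3])) out[, , k] <- fill_holes_slice(mask3d[, , k])
  out
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
# Zero-padded boundaries; kernel truncated at 3 sigma.
smooth_gauss3 <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3L)
  smooth_mat <- function(n, s) {
    if (s <= 0) return(diag(n))
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    m <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      src <- idx + o
      ok <- src >= 1L & src <= n
      m[cbind(idx[ok], src[ok])] <- m[cbind(idx[ok], src[ok])] + k[o + r + 1L]
    }
    m
  }
  # axis 1
  x <- matrix(arr, d[1], d[2] * d[3])
  x <- smooth_mat(d[1], sigma[1]) %*% x
  arr <- array(x, d)
  # axis 2
  a <- aperm(arr, c(2L, 1L, 3L))
  x <- matrix(a, d[2], d[1] * d[3])
  x <- smooth_mat(d[2], sigma[2]) %*% x
  arr <- aperm(array(x, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
  # axis 3
  a <- aperm(arr, c(3L, 1L, 2L))
  x <- matrix(a, d[3], d[1] * d[2])
  x <- smooth_mat(d[3], sigma[3]) %*% x
  aperm(array(x, c(d[3], d[1], d[2])), c(2L, 3L, 1L))
}

#' Bilinear resize of a 2D array, preserving the value range
#'
#' Resizes with align-corners bilinear interpolation, then linearly rescales
#' the result so its minimum and maximum equal those of the source exactly
#' (range-preserving interpolation). A constant input stays constant.
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @param preserve_range rescale the output to the exact source range
#'   (default). Set `FALSE` for plain interpolation, e.g. when resizing
#'   probability maps whose values must not be rescaled.
#' @return `out_h` x `out_w` numeric matrix with `range(out) == range(mat)`
#'   when `preserve_range` is `TRUE`.
#' @export
resize_bilinear <- function(mat, out_h, out_w, preserve_range = TRUE) {
  d <- dim(mat)
  if (out_h < 1 || out_w < 1)
    stop_dceseg("output dimensions must be positive", "dceseg_value_error")
  if (out_h == d[1] && out_w == d[2]) return(mat)
  coord <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(1, n_out)
    else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ri <- coord(out_h, d[1]); ci <- coord(out_w, d[2])
  r0 <- pmin(floor(ri), d[1] - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), d[2] - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  if (d[1] == 1L) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (d[2] == 1L) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  r1 <- pmin(r0 + 1L, d[1]); c1 <- pmin(c0 + 1L, d[2])
  w00 <- outer(1 - fr, 1 - fc); w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc);     w11 <- outer(fr, fc)
  out <- w00 * mat[r0, c0, drop = FALSE] + w01 * mat[r0, c1, drop = FALSE] +
         w10 * mat[r1, c0, drop = FALSE] + w11 * mat[r1, c1, drop = FALSE]
  if (preserve_range) {
    src <- range(mat)
    cur <- range(out)
    if (diff(cur) > 0 && diff(src) > 0)
      out <- src[1] + (out - cur[1]) * diff(src) / diff(cur)
    else out[] <- mean(src)
  }
  out
}

# Nearest-neighbour resize for binary targets.
resize_nearest <- function(mat, out_h, out_w) {
  d <- dim(mat)
  coord <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(1L, n_out)
    else pmax(1L, pmin(n_in, round(1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1))))
  }
  mat[coord(out_h, d[1]), coord(out_w, d[2]), drop = FALSE]
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards so generators are pure functions of their
# seed without disturbing user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
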