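# 3D convolutional primitives. Tensors are arrays (H, W, D, C); the 3D
# network processes one volume at a time (batch size 1). Convolutions are
# 3x3x3 "same" via the compiled im2col kernel; pooling is 2x2 in-plane with
# the axial factor configurable (1 = in-plane only, for thin lesions).

conv3d_fwd <- function(x, W, b, k = 3L) {
  d <- dim(x)
  P <- im2col3d_cpp(x, d[1], d[2], d[3], d[4], k)
  y <- P %*% W
  y <- sweep(y, 2L, b, `+`)
  dim(y) <- c(d[1], d[2], d[3], length(b))
  y
}

conv3d_bwd <- function(x, W, dy, k = 3L) {
  d <- dim(x)
  dymat <- dy
  dim(dymat) <- c(d[1] * d[2] * d[3], dim(W)[2])
  P <- im2col3d_cpp(x, d[1], d[2], d[3], d[4], k)
  list(dW = crossprod(P, dymat),
       db = colSums(dymat),
       dx = col2im3d_cpp(dymat %*% t(W), d[1], d[2], d[3], d[4], k))
}

maxpool3d_fwd <- function(x, kz = 1L) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  if (kz == 1L) {
    pmax(pmax(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE]),
         pmax(x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE]))
  } else {
    k1 <- seq(1L, d[3], 2L); k2 <- k1 + 1L
    y <- NULL
    for (kk in list(k1, k2)) {
      cand <- pmax(pmax(x[i1, j1, kk, , drop = FALSE], x[i2, j1, kk, , drop = FALSE]),
                   pmax(x[i1, j2, kk, , drop = FALSE], x[i2, j2, kk, , drop = FALSE]))
      y <- if (is.null(y)) cand else pmax(y, cand)
    }
    y
  }
}

maxpool3d_bwd <- function(x, y, dy, kz = 1L) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  ks <- if (kz == 1L) list(seq_len(d[3])) else {
    k1 <- seq(1L, d[3], 2L)
    list(k1, k1 + 1L)
  }
  dx <- array(0, d)
  taken <- array(FALSE, dim(y))
  for (kk in ks) for (ii in list(i1, i2)) for (jj in list(j1, j2)) {
    m <- (x[ii, jj, kk, , drop = FALSE] == y) & !taken
    taken <- taken | m
    dx[ii, jj, kk, ] <- dx[ii, jj, kk, , drop = FALSE] + dy * m
  }
  dx
}

upsample3d_fwd <- function(x, kz = 1L) {
  d <- dim(x)
  zk <- if (kz == 1L) seq_len(d[3]) else rep(seq_len(d[3]), each = 2L)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), zk, , drop = FALSE]
}

upsample3d_bwd <- function(dy, kz = 1L) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  s <- dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
  if (kz == 1L) s
  else {
    k1 <- seq(1L, dim(s)[3], 2L)
    s[, , k1, , drop = FALSE] + s[, , k1 + 1L, , drop = FALSE]
  }
}
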