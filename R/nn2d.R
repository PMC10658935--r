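# 2D convolutional primitives.
#
# Tensors are arrays (H, W, N, C) — batch of N slices, channels last — so
# the (H*W*N) x (k*k*C) patch matrix produced by the compiled im2col kernel
# maps onto the array without any permutation, and convolution is a single
# BLAS matmul against a (k*k*C) x Cout weight matrix. Backward passes
# rebuild the patch matrix from the cached layer input.

conv2d_fwd <- function(x, W, b, k = 3L) {
  d <- dim(x)
  P <- im2col2d_cpp(x, d[1], d[2], d[3], d[4], k)
  y <- P %*% W
  y <- sweep(y, 2L, b, `+`)
  dim(y) <- c(d[1], d[2], d[3], length(b))
  y
}

conv2d_bwd <- function(x, W, dy, k = 3L) {
  d <- dim(x)
  cout <- dim(W)[2]
  dymat <- dy
  dim(dymat) <- c(d[1] * d[2] * d[3], cout)
  P <- im2col2d_cpp(x, d[1], d[2], d[3], d[4], k)
  list(dW = crossprod(P, dymat),
       db = colSums(dymat),
       dx = col2im2d_cpp(dymat %*% t(W), d[1], d[2], d[3], d[4], k))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

maxpool2d_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  pmax(pmax(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE]),
       pmax(x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE]))
}

# Gradient routed to the first (row-major priority) occurrence of the max.
maxpool2d_bwd <- function(x, y, dy) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  taken <- array(FALSE, dim(y))
  for (blk in list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))) {
    m <- (x[blk[[1]], blk[[2]], , , drop = FALSE] == y) & !taken
    taken <- taken | m
    dx[blk[[1]], blk[[2]], , ] <- dy * m
  }
  dx
}

upsample2d_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2d_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

# Channel (4th axis) concatenation/split, shared by the 2D and 3D arms.
concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

split_ch <- function(dy, c1) {
  d <- dim(dy)
  list(dy[, , , seq_len(c1), drop = FALSE],
       dy[, , , (c1 + 1L):d[4], drop = FALSE])
}

# Numerically stable binary cross-entropy on logits; grad is w.r.t. logits.
bce_with_logits <- function(z, y) {
  sp <- pmax(z, 0) + log1p(exp(-abs(z)))
  loss <- mean(sp - y * z)
  grad <- (1 / (1 + exp(-z)) - y) / length(z)
  list(loss = loss, grad = grad)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

he_init <- function(nrow_, ncol_) {
  matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / nrow_)), nrow_, ncol_)
}

# One Adam update over a flat named list of parameters.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}
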