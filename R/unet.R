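# U-Net model: configuration, initialization, forward/backward passes and
# Adam training. The same encoder-decoder topology serves the 2D and 3D
# arms; only the convolution/pooling primitives differ.

#' U-Net configuration
#'
#' Defaults are the canonical full-scale architecture (4 down-sampling
#' blocks, 64 base filters, 256x256 inputs). Tests and desk-scale runs use
#' smaller settings, e.g. `unet_config("2d", levels = 3, base_filters = 16,
#' input_size = 64)`.
#'
#' @param arch `"2d"` (slice network, quasi-3D assembly) or `"3d"`.
#' @param levels number of resolution levels (>= 2); `levels - 1` poolings.
#' @param base_filters channels at the first level; doubled per level.
#' @param input_size in-plane input size; must be divisible by
#'   `2^(levels-1)`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (2D; the 3D arm trains volume-by-volume).
#' @param axial_pool for the 3D arm, whether pooling also halves the slice
#'   axis. Off by default: breast lesion VOIs often have too few slices to
#'   pool axially, so pooling is in-plane only unless lesions are thick.
#' @param threshold probability threshold converting maps to binary masks
#'   (0.25 for the 2D arm, 0.23 for the 3D arm).
#' @export
unet_config <- function(arch = c("2d", "3d"), levels = 5L, base_filters = 64L,
                        input_size = 256L, lr = 1e-3,
                        batch_size = if (arch == "2d") 8L else 1L,
                        axial_pool = FALSE,
                        threshold = if (arch == "2d") 0.25 else 0.23) {
  arch <- match.arg(arch)
  if (levels < 2L) stop_dceseg("levels must be >= 2", "dceseg_config_error")
  if (input_size %% 2L^(levels - 1L) != 0L)
    stop_dceseg("input_size must be divisible by 2^(levels-1)", "dceseg_config_error")
  structure(list(arch = arch, levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 input_size = as.integer(input_size), lr = lr,
                 batch_size = as.integer(batch_size),
                 axial_pool = isTRUE(axial_pool), threshold = threshold),
            class = "unet_config")
}

unet_channels <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$levels) - 1L)

# Primitive dispatch per architecture; kz is the axial pooling factor.
unet_ops <- function(cfg) {
  if (cfg$arch == "2d") {
    list(kvol = 9L,
         conv_f = conv2d_fwd, conv_b = conv2d_bwd,
         pool_f = maxpool2d_fwd, pool_b = maxpool2d_bwd,
         up_f = upsample2d_fwd, up_b = upsample2d_bwd,
         cat_f = concat_ch, cat_b = split_ch,
         nch = function(x) dim(x)[4])
  } else {
    kz <- if (cfg$axial_pool) 2L else 1L
    list(kvol = 27L,
         conv_f = conv3d_fwd, conv_b = conv3d_bwd,
         pool_f = function(x) maxpool3d_fwd(x, kz),
         pool_b = function(x, y, dy) maxpool3d_bwd(x, y, dy, kz),
         up_f = function(x) upsample3d_fwd(x, kz),
         up_b = function(dy) upsample3d_bwd(dy, kz),
         cat_f = concat_ch, cat_b = split_ch,
         nch = function(x) dim(x)[4])
  }
}

unet_init_params <- function(cfg, seed) {
  ch <- unet_channels(cfg)
  L <- cfg$levels
  kv <- if (cfg$arch == "2d") 9L else 27L
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(L - 1L)) {
      p[[sprintf("enc%d.W1", l)]] <- he_init(kv * cin, ch[l])
      p[[sprintf("enc%d.b1", l)]] <- numeric(ch[l])
      p[[sprintf("enc%d.W2", l)]] <- he_init(kv * ch[l], ch[l])
      p[[sprintf("enc%d.b2", l)]] <- numeric(ch[l])
      cin <- ch[l]
    }
    p[["bott.W1"]] <- he_init(kv * ch[L - 1L], ch[L])
    p[["bott.b1"]] <- numeric(ch[L])
    p[["bott.W2"]] <- he_init(kv * ch[L], ch[L])
    p[["bott.b2"]] <- numeric(ch[L])
    for (l in rev(seq_len(L - 1L))) {
      p[[sprintf("up%d.W", l)]] <- he_init(kv * ch[l + 1L], ch[l])
      p[[sprintf("up%d.b", l)]] <- numeric(ch[l])
      p[[sprintf("dec%d.W1", l)]] <- he_init(kv * 2L * ch[l], ch[l])
      p[[sprintf("dec%d.b1", l)]] <- numeric(ch[l])
      p[[sprintf("dec%d.W2", l)]] <- he_init(kv * ch[l], ch[l])
      p[[sprintf("dec%d.b2", l)]] <- numeric(ch[l])
    }
    p[["out.W"]] <- he_init(ch[1L], 1L)
    p[["out.b"]] <- numeric(1L)
    p
  })
}

unet_forward <- function(params, x, cfg, keep_cache = TRUE) {
  ops <- unet_ops(cfg)
  L <- cfg$levels
  cache <- list(enc = vector("list", L - 1L), dec = vector("list", L - 1L))
  skips <- vector("list", L - 1L)
  h <- x
  for (l in seq_len(L - 1L)) {
    xin <- h
    a1 <- ops$conv_f(xin, params[[sprintf("enc%d.W1", l)]], params[[sprintf("enc%d.b1", l)]])
    z1 <- relu_fwd(a1)
    a2 <- ops$conv_f(z1, params[[sprintf("enc%d.W2", l)]], params[[sprintf("enc%d.b2", l)]])
    z2 <- relu_fwd(a2)
    pooled <- ops$pool_f(z2)
    if (keep_cache) cache$enc[[l]] <- list(xin = xin, a1 = a1, z1 = z1, a2 = a2,
                                           z2 = z2, pooled = pooled)
    skips[[l]] <- z2
    h <- pooled
  }
  bx <- h
  ba1 <- ops$conv_f(bx, params[["bott.W1"]], params[["bott.b1"]])
  bz1 <- relu_fwd(ba1)
  ba2 <- ops$conv_f(bz1, params[["bott.W2"]], params[["bott.b2"]])
  h <- relu_fwd(ba2)
  if (keep_cache) cache$bott <- list(bx = bx, ba1 = ba1, bz1 = bz1, ba2 = ba2, bz2 = h)
  for (l in rev(seq_len(L - 1L))) {
    u <- ops$up_f(h)
    au <- ops$conv_f(u, params[[sprintf("up%d.W", l)]], params[[sprintf("up%d.b", l)]])
    zu <- relu_fwd(au)
    ct <- ops$cat_f(skips[[l]], zu)
    a1 <- ops$conv_f(ct, params[[sprintf("dec%d.W1", l)]], params[[sprintf("dec%d.b1", l)]])
    z1 <- relu_fwd(a1)
    a2 <- ops$conv_f(z1, params[[sprintf("dec%d.W2", l)]], params[[sprintf("dec%d.b2", l)]])
    z2 <- relu_fwd(a2)
    if (keep_cache) cache$dec[[l]] <- list(u = u, au = au, zu = zu, ct = ct,
                                           a1 = a1, z1 = z1, a2 = a2, z2 = z2)
    h <- z2
  }
  logits <- ops$conv_f(h, params[["out.W"]], params[["out.b"]], k = 1L)
  if (keep_cache) cache$out_in <- h
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

unet_backward <- function(params, cfg, cache, dlogits) {
  ops <- unet_ops(cfg)
  L <- cfg$levels
  g <- list()
  bo <- ops$conv_b(cache$out_in, params[["out.W"]], dlogits, k = 1L)
  g[["out.W"]] <- bo$dW; g[["out.b"]] <- bo$db
  dh <- bo$dx
  dskips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    da2 <- relu_bwd(dc$a2, dh)
    b2 <- ops$conv_b(dc$z1, params[[sprintf("dec%d.W2", l)]], da2)
    g[[sprintf("dec%d.W2", l)]] <- b2$dW; g[[sprintf("dec%d.b2", l)]] <- b2$db
    da1 <- relu_bwd(dc$a1, b2$dx)
    b1 <- ops$conv_b(dc$ct, params[[sprintf("dec%d.W1", l)]], da1)
    g[[sprintf("dec%d.W1", l)]] <- b1$dW; g[[sprintf("dec%d.b1", l)]] <- b1$db
    parts <- ops$cat_b(b1$dx, ops$nch(cache$enc[[l]]$z2))
    dskips[[l]] <- parts[[1L]]
    dau <- relu_bwd(dc$au, parts[[2L]])
    bu <- ops$conv_b(dc$u, params[[sprintf("up%d.W", l)]], dau)
    g[[sprintf("up%d.W", l)]] <- bu$dW; g[[sprintf("up%d.b", l)]] <- bu$db
    dh <- ops$up_b(bu$dx)
  }
  bc <- cache$bott
  dba2 <- relu_bwd(bc$ba2, dh)
  b2 <- ops$conv_b(bc$bz1, params[["bott.W2"]], dba2)
  g[["bott.W2"]] <- b2$dW; g[["bott.b2"]] <- b2$db
  dba1 <- relu_bwd(bc$ba1, b2$dx)
  b1 <- ops$conv_b(bc$bx, params[["bott.W1"]], dba1)
  g[["bott.W1"]] <- b1$dW; g[["bott.b1"]] <- b1$db
  dh <- b1$dx
  for (l in rev(seq_len(L - 1L))) {
    ec <- cache$enc[[l]]
    dz2 <- ops$pool_b(ec$z2, ec$pooled, dh) + dskips[[l]]
    da2 <- relu_bwd(ec$a2, dz2)
    b2 <- ops$conv_b(ec$z1, params[[sprintf("enc%d.W2", l)]], da2)
    g[[sprintf("enc%d.W2", l)]] <- b2$dW; g[[sprintf("enc%d.b2", l)]] <- b2$db
    da1 <- relu_bwd(ec$a1, b2$dx)
    b1 <- ops$conv_b(ec$xin, params[[sprintf("enc%d.W1", l)]], da1)
    g[[sprintf("enc%d.W1", l)]] <- b1$dW; g[[sprintf("enc%d.b1", l)]] <- b1$db
    dh <- b1$dx
  }
  g
}

# min-max normalize an image tensor to [0, 1]; constant inputs map to 0.
normalize01 <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(array(0, dim(x)))
  (x - rng[1]) / diff(rng)
}

# normalize against a fixed (e.g. per-VOI) range.
normalize_to <- function(x, rng) {
  if (diff(rng) <= 0) return(array(0, dim(x)))
  (x - rng[1]) / diff(rng)
}

#' Train a U-Net on slice or volume samples
#'
#' Adam + binary cross-entropy on logits; inputs are min-max normalized to
#' [0, 1]. For the 2D arm samples are shuffled into minibatches each epoch;
#' the 3D arm trains volume-by-volume. Training is reproducible given
#' (samples, config, epochs, seed).
#'
#' @param samples list of samples: `$image` (H x W matrix for 2D,
#'   H x W x D array for 3D) and `$target` (binary, same shape).
#' @param config a [unet_config()].
#' @param epochs number of passes over the training set (>= 1).
#' @param seed seed for weight initialization and shuffling.
#' @return object of class `dce_unet` with `params`, `config`, `loss_log`
#'   (mean BCE per epoch).
#' @export
train_unet <- function(samples, config, epochs = 30L, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  if (length(samples) == 0)
    stop_dceseg("empty training set", "dceseg_config_error")
  if (epochs < 1L)
    stop_dceseg("epochs must be >= 1", "dceseg_config_error")
  for (s in samples)
    if (!all(s$target %in% c(0, 1)))
      stop_dceseg("targets must be binary", "dceseg_config_error")

  params <- unet_init_params(config, seed)
  state <- adam_init(params)
  loss_log <- numeric(epochs)
  n <- length(samples)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      if (config$arch == "2d") {
        bs <- config$batch_size
        starts <- seq(1L, n, by = bs)
        for (st in starts) {
          idx <- ord[st:min(st + bs - 1L, n)]
          sz <- dim(samples[[idx[1]]]$image)
          x <- array(0, c(sz[1], sz[2], length(idx), 1L))
          y <- array(0, c(sz[1], sz[2], length(idx), 1L))
          for (i in seq_along(idx)) {
            s <- samples[[idx[i]]]
            x[, , i, 1L] <- if (is.null(s$norm_range)) normalize01(s$image)
                            else normalize_to(s$image, s$norm_range)
            y[, , i, 1L] <- s$target
          }
          fw <- unet_forward(params, x, config)
          lo <- bce_with_logits(fw$logits, y)
          grads <- unet_backward(params, config, fw$cache, lo$grad)
          upd <- adam_step(params, grads, state, lr = config$lr)
          params <- upd$params; state <- upd$state
          losses <- c(losses, lo$loss)
        }
      } else {
        for (i in ord) {
          sz <- dim(samples[[i]]$image)
          x <- array(normalize01(samples[[i]]$image), c(sz, 1L))
          y <- array(samples[[i]]$target, c(sz, 1L))
          fw <- unet_forward(params, x, config)
          lo <- bce_with_logits(fw$logits, y)
          grads <- unet_backward(params, config, fw$cache, lo$grad)
          upd <- adam_step(params, grads, state, lr = config$lr)
          params <- upd$params; state <- upd$state
          losses <- c(losses, lo$loss)
        }
      }
      loss_log[ep] <- mean(losses)
    }
  })
  structure(list(params = params, config = config, loss_log = loss_log,
                 seed = as.integer(seed)),
            class = "dce_unet")
}

#' @export
print.dce_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dce_unet> %s: %d levels, %d base filters, input %d; %d epochs, final BCE %.4f\n",
              cfg$arch, cfg$levels, cfg$base_filters, cfg$input_size,
              length(x$loss_log), utils::tail(x$loss_log, 1)))
  invisible(x)
}

# Forward a normalized input tensor through a trained net -> probabilities.
unet_probability <- function(model, x) {
  if (!inherits(model, "dce_unet") || is.null(model$params))
    stop_dceseg("model is not a trained U-Net", "dceseg_state_error")
  fw <- unet_forward(model$params, x, model$config, keep_cache = FALSE)
  sigmoid(fw$logits)
}
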