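# Core network machinery: analytic gradients, determinism, learning sanity.

jitter_params <- function(params, seed = 1L) {
  # break exact-zero pre-activations so finite differences avoid ReLU kinks
  with_seed(seed, lapply(params, function(p) p + rnorm(length(p), sd = 1e-3)))
}

gradcheck_max_err <- function(cfg, x, y, n_per_param = 3L) {
  params <- jitter_params(unet_init_params(cfg, 1L))
  fw <- unet_forward(params, x, cfg)
  lo <- bce_with_logits(fw$logits, y)
  g <- unet_backward(params, cfg, fw$cache, lo$grad)
  lossfun <- function(p)
    bce_with_logits(unet_forward(p, x, cfg, keep_cache = FALSE)$logits, y)$loss
  err <- 0
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(n_per_param, length(params[[nm]])))) {
      h <- 1e-5
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h; lp <- lossfun(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h; lm <- lossfun(p2)
      num <- (lp - lm) / (2 * h)
      err <- max(err, abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])))
    }
  }
  err
}

test_that("backpropagation matches finite differences (2D)", {
  cfg <- unet_config("2d", levels = 2L, base_filters = 2L, input_size = 8L,
                     batch_size = 2L)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  y <- array(rbinom(128, 1, 0.4), c(8, 8, 2, 1))
  expect_lt(gradcheck_max_err(cfg, x, y), 1e-5)
})

test_that("backpropagation matches finite differences (3D, both pooling modes)", {
  set.seed(3)
  for (ap in c(FALSE, TRUE)) {
    cfg <- unet_config("3d", levels = 2L, base_filters = 2L, input_size = 8L,
                       axial_pool = ap)
    d3 <- if (ap) 4L else 3L
    x <- array(rnorm(8 * 8 * d3), c(8, 8, d3, 1))
    y <- array(rbinom(8 * 8 * d3, 1, 0.4), c(8, 8, d3, 1))
    expect_lt(gradcheck_max_err(cfg, x, y), 1e-5)
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(11)
  samples <- lapply(1:12, function(i) {
    img <- matrix(rnorm(16 * 16, sd = 0.1), 16, 16)
    r0 <- sample(4:10, 1); c0 <- sample(4:10, 1)
    tgt <- matrix(0, 16, 16); tgt[r0:(r0 + 4), c0:(c0 + 4)] <- 1
    img <- img + tgt
    list(image = img, target = tgt)
  })
  cfg <- unet_config("2d", levels = 2L, base_filters = 4L, input_size = 16L,
                     batch_size = 4L)
  m1 <- train_unet(samples, cfg, epochs = 6L, seed = 9L)
  expect_lt(tail(m1$loss_log, 1), m1$loss_log[1])

  m2 <- train_unet(samples, cfg, epochs = 6L, seed = 9L)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training configurations are rejected", {
  cfg <- unet_config("2d", levels = 2L, base_filters = 2L, input_size = 8L)
  s <- list(list(image = matrix(0, 8, 8), target = matrix(0, 8, 8)))
  expect_error(train_unet(list(), cfg), class = "dceseg_config_error")
  expect_error(train_unet(s, cfg, epochs = 0L), class = "dceseg_config_error")
  bad <- list(list(image = matrix(0, 8, 8), target = matrix(0.5, 8, 8)))
  expect_error(train_unet(bad, cfg), class = "dceseg_config_error")
  expect_error(unet_config("2d", levels = 4L, input_size = 12L),
               class = "dceseg_config_error")
})

test_that("probabilities are in [0,1] and inference is deterministic", {
  cfg <- unet_config("2d", levels = 2L, base_filters = 2L, input_size = 8L)
  model <- structure(list(params = unet_init_params(cfg, 1L), config = cfg,
                          loss_log = 0.5), class = "dce_unet")
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  p1 <- unet_probability(model, x)
  p2 <- unet_probability(model, x)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)
  # constant-zero input still yields valid probabilities
  p0 <- unet_probability(model, array(0, c(8, 8, 1, 1)))
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("batched slice prediction equals slice-by-slice prediction", {
  cfg <- unet_config("2d", levels = 2L, base_filters = 3L, input_size = 16L)
  model <- structure(list(params = unet_init_params(cfg, 4L), config = cfg,
                          loss_log = 0.5), class = "dce_unet")
  set.seed(13)
  x <- array(rnorm(16 * 16 * 5), c(16, 16, 5, 1))
  batch <- unet_probability(model, x)
  for (k in 1:5) {
    single <- unet_probability(model, x[, , k, , drop = FALSE])
    expect_identical(batch[, , k, 1], single[, , 1, 1])
  }
})
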