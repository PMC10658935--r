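# Shared fixtures: fixed-spacing protocols, small phantom builders and a
# hand-built minimal case for feature-extraction arithmetic.

fixed_protocol <- function(noise = 0.05, background = 0.2) {
  dce_protocol(spacing_mm = c(row = 0.8, col = 0.8, slice = 2),
               noise_sd_frac = noise, background_frac = background)
}

mass_case <- function(d = 10, seed = 5L, noise = 0.05, background = 0.2,
                      pathology = "malignant") {
  generate_dce_case(lesion_spec("mass", pathology, d, seed = seed),
                    fixed_protocol(noise, background))
}

nonmass_case <- function(d = 10, seed = 9L, noise = 0.05) {
  generate_dce_case(lesion_spec("nonmass", "malignant", d, seed = seed),
                    fixed_protocol(noise))
}

# A tiny hand-built case: 3x3x1 VOI grid, 3 timepoints, prescribed values.
tiny_case <- function(s0 = 100, s1 = 150, s2 = 200) {
  series <- array(0, c(3, 3, 1, 3))
  series[, , , 1] <- s0; series[, , , 2] <- s1; series[, , , 3] <- s2
  structure(list(series = series,
                 spacing_mm = c(row = 1, col = 1, slice = 1),
                 timepoints_s = c(0, 75, 150),
                 truth_mask = array(FALSE, c(3, 3, 1)),
                 voi = lesion_voi(c(1, 3), c(1, 3), 1, 1),
                 spec = lesion_spec("mass", "malignant", 5),
                 case_id = "tiny"),
            class = "dce_case")
}

random_mask <- function(h, w, p = 0.4) {
  matrix(stats::runif(h * w) < p, h, w)
}

# Brute-force slicewise Hausdorff oracle: double loop over boundary pixels.
oracle_hausdorff <- function(a, b, spacing = c(1, 1)) {
  bd <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!m[i, j]) next
      nb4 <- c(if (i > 1) m[i - 1, j] else FALSE,
               if (i < d[1]) m[i + 1, j] else FALSE,
               if (j > 1) m[i, j - 1] else FALSE,
               if (j < d[2]) m[i, j + 1] else FALSE)
      if (!all(nb4)) out <- rbind(out, c(i, j))
    }
    out
  }
  ea <- !any(a); eb <- !any(b)
  if (ea && eb) return(0)
  if (ea || eb) return(NA_real_)
  pa <- bd(a); pb <- bd(b)
  h <- function(p1, p2) {
    mx <- 0
    for (i in seq_len(nrow(p1))) {
      mn <- Inf
      for (j in seq_len(nrow(p2))) {
        dd <- sqrt(((p1[i, 1] - p2[j, 1]) * spacing[1])^2 +
                   ((p1[i, 2] - p2[j, 2]) * spacing[2])^2)
        if (dd < mn) mn <- dd
      }
      if (mn > mx) mx <- mn
    }
    mx
  }
  max(h(pa, pb), h(pb, pa))
}

# Brute-force FCM reference: plain alternating updates from given centroids.
oracle_fcm <- function(x, v0, m = 2, tol = 1e-5, max_iter = 100) {
  x <- as.matrix(x); v <- as.matrix(v0)
  cc <- nrow(v); n <- nrow(x)
  u <- matrix(1 / cc, n, cc)
  for (it in seq_len(max_iter)) {
    d2 <- matrix(0, n, cc)
    for (i in seq_len(cc)) for (k in seq_len(n))
      d2[k, i] <- sum((x[k, ] - v[i, ])^2)
    d2 <- pmax(d2, .Machine$double.eps)
    u_new <- matrix(0, n, cc)
    for (k in seq_len(n)) for (i in seq_len(cc))
      u_new[k, i] <- 1 / sum((d2[k, i] / d2[k, ])^(1 / (m - 1)))
    for (i in seq_len(cc))
      v[i, ] <- colSums(u_new[, i]^m * x) / sum(u_new[, i]^m)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(u = u, v = v)
}

# Exact signed-rank oracle: enumerate all 2^n sign assignments on the
# tie-averaged ranks of |d|.
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact Mann-Whitney oracle: enumerate all C(n+m, n) group assignments.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
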