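test_that("dice handles identity, disjoint and partial overlap", {
  a <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3) > 0
  expect_identical(dice(a, a), 1)
  b <- !a
  expect_identical(dice(a, b), 0)

  x <- matrix(FALSE, 4, 4); x[1:2, 1:2] <- TRUE               # |A| = 4
  y <- matrix(FALSE, 4, 4)
  y[cbind(c(1, 2, 2, 3, 3, 3), c(2, 1, 2, 1, 2, 3))] <- TRUE  # |B| = 6
  expect_identical(sum(x & y), 3L)
  expect_equal(dice(x, y), 0.6)

  expect_identical(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               class = "dceseg_integrity_error")
})

test_that("slicewise Hausdorff distances respect anisotropic spacing", {
  a <- matrix(FALSE, 5, 5); a[2, 2] <- TRUE
  expect_identical(hausdorff_slice(a, a), 0)

  b <- matrix(FALSE, 5, 5); b[2, 5] <- TRUE
  expect_equal(hausdorff_slice(a, b, c(1, 1)), 3)

  A <- matrix(FALSE, 1, 4); A[1, c(1, 4)] <- TRUE
  B <- matrix(FALSE, 1, 4); B[1, 1] <- TRUE
  expect_equal(hausdorff_slice(A, B, c(1.0, 0.5)), 1.5)

  expect_true(is.na(hausdorff_slice(a, matrix(FALSE, 5, 5))))
  expect_identical(hausdorff_slice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
})

test_that("dice and hausdorff match brute-force oracles on random masks", {
  set.seed(99)
  for (i in 1:200) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    a <- random_mask(h, w); b <- random_mask(h, w)
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    expect_identical(dice(a, b),
                     if (sum(a) + sum(b) == 0) 1 else 2 * sum(a & b) / (sum(a) + sum(b)))
    expect_equal(hausdorff_slice(a, b, sp), oracle_hausdorff(a, b, sp),
                 tolerance = 1e-12)
  }
})

test_that("metrics are symmetric and scale-covariant", {
  set.seed(5)
  for (i in 1:20) {
    a <- random_mask(8, 8); b <- random_mask(8, 8)
    expect_identical(dice(a, b), dice(b, a))
    h1 <- hausdorff_slice(a, b, c(1, 1))
    expect_equal(h1, hausdorff_slice(b, a, c(1, 1)))
    if (!is.na(h1)) expect_equal(hausdorff_slice(a, b, c(2, 2)), 2 * h1)
  }
})

test_that("per-lesion HD is the median over doubly non-empty slices", {
  mk <- function(shift) {
    m <- array(FALSE, c(8, 8, 3))
    m[3:5, (3 + shift):(5 + shift), 1:3] <- TRUE
    m
  }
  sp <- c(row = 1, col = 1, slice = 2)
  expect_identical(lesion_median_hd(mk(0), mk(0), sp), 0)
  expect_equal(lesion_median_hd(mk(1), mk(0), sp), 1)

  pred <- array(FALSE, c(8, 8, 3))
  expect_true(is.na(lesion_median_hd(pred, mk(0), sp)))

  # even slice count: mean-of-middle-two median convention
  a <- array(FALSE, c(6, 6, 2)); b <- array(FALSE, c(6, 6, 2))
  a[2, 2, 1] <- TRUE; b[2, 3, 1] <- TRUE   # HD 1
  a[2, 2, 2] <- TRUE; b[2, 5, 2] <- TRUE   # HD 3
  expect_equal(lesion_median_hd(a, b, sp), 2)
})

test_that("center slice index follows the floor convention", {
  expect_identical(center_slice_index(lesion_voi(c(1, 4), c(1, 4), 2, 6)), 4L)
  expect_identical(center_slice_index(lesion_voi(c(1, 4), c(1, 4), 2, 5)), 3L)
  expect_identical(center_slice_index(lesion_voi(c(1, 4), c(1, 4), 7, 7)), 7L)
})

test_that("effective diameter inverts the circle-area formula", {
  one <- matrix(FALSE, 20, 20); one[1, 1] <- TRUE
  expect_equal(effective_diameter(one, c(1, 1)), 2 / sqrt(pi), tolerance = 1e-12)

  hundred <- matrix(FALSE, 20, 20); hundred[1:10, 1:10] <- TRUE
  expect_equal(effective_diameter(hundred, c(1, 1)), 2 * sqrt(100 / pi),
               tolerance = 1e-6)
  expect_equal(effective_diameter(hundred, c(2, 2)), 2 * 2 * sqrt(100 / pi),
               tolerance = 1e-6)
  expect_error(effective_diameter(matrix(FALSE, 3, 3)), class = "dceseg_value_error")
})

test_that("evaluate_lesion aggregates volume, center and failure metrics", {
  voi <- lesion_voi(c(1, 8), c(1, 8), 1, 3)
  sp <- c(row = 1, col = 1, slice = 2)
  ref <- array(FALSE, c(8, 8, 3)); ref[3:5, 3:5, 1:3] <- TRUE

  rec <- evaluate_lesion(ref, ref, voi, sp, lesion_id = "l1")
  expect_equal(rec$dsc, 1)
  expect_equal(rec$median_hd_mm, 0)
  expect_equal(rec$center_dsc, 1)
  expect_false(rec$failed)

  empty <- array(FALSE, c(8, 8, 3))
  rec2 <- evaluate_lesion(empty, ref, voi, sp, lesion_id = "l2")
  expect_identical(rec2$dsc, 0)
  expect_true(is.na(rec2$median_hd_mm))
  expect_true(rec2$failed)

  shifted <- array(FALSE, c(8, 8, 3)); shifted[3:5, 4:6, 1:3] <- TRUE
  rec3 <- evaluate_lesion(shifted, ref, voi, sp, lesion_id = "l3")
  expect_equal(rec3$median_hd_mm, 1)
})
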