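test_that("mass shapes hit the requested effective diameter on the center slice", {
  sp <- c(row = 0.5, col = 0.5, slice = 2)
  spec <- lesion_spec("mass", "malignant", 10, seed = 42L)
  m <- generate_lesion_shape(spec, sp, c(48, 48, 11))
  cs <- center_of_support(m)
  expect_equal(effective_diameter(m[, , cs], sp[c("row", "col")]), 10,
               tolerance = 0.5 / 10)
})

test_that("nonmass shapes are disconnected in the center slice at matched area", {
  sp <- c(row = 0.5, col = 0.5, slice = 2)
  spec <- lesion_spec("nonmass", "malignant", 10, seed = 7L)
  m <- generate_lesion_shape(spec, sp, c(80, 80, 11))
  cs <- center_of_support(m)
  expect_gte(max(label_components(m[, , cs], connectivity = 4L)), 2L)
  expect_equal(effective_diameter(m[, , cs], sp[c("row", "col")]), 10,
               tolerance = 1 / 10)
})

test_that("a diameter exceeding the volume extent is a geometry error", {
  expect_error(
    generate_lesion_shape(lesion_spec("mass", "malignant", 1000, seed = 1L),
                          c(row = 0.5, col = 0.5, slice = 2), c(64, 64, 8)),
    class = "dceseg_geometry_error")
})

test_that("size calibration holds over many generated masses", {
  sp <- c(row = 0.8, col = 0.8, slice = 2.5)
  errs <- vapply(1:100, function(i) {
    d <- runif(1, 4, 22)
    m <- generate_lesion_shape(lesion_spec("mass", "malignant", d, seed = i),
                               sp, c(56, 56, 13))
    cs <- center_of_support(m)
    abs(effective_diameter(m[, , cs], sp[c("row", "col")]) - d)
  }, numeric(1))
  expect_lte(mean(errs), 0.8)  # one in-plane voxel
})

test_that("zero-noise cases follow the closed-form enhancement model", {
  case <- mass_case(noise = 0, background = 0)
  curve <- enhancement_curve(case$spec$kinetic, case$timepoints_s)
  pre <- mean(case$series[, , , 1][case$truth_mask])
  post1 <- mean(case$series[, , , 2][case$truth_mask])
  expect_equal(post1, (1 + curve[2]) * pre, tolerance = 1e-12)
})

test_that("case generation is a pure function of (spec, seed)", {
  a <- mass_case(seed = 77L)
  b <- mass_case(seed = 77L)
  expect_identical(a$series, b$series)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$voi, b$voi)
  c2 <- mass_case(seed = 78L)
  expect_false(identical(a$series, c2$series))
})

test_that("truth mask sits strictly inside the VOI with the configured margin", {
  for (case in list(mass_case(seed = 3L), nonmass_case(seed = 4L))) {
    idx <- which(case$truth_mask, arr.ind = TRUE)
    voi <- case$voi
    expect_true(all(idx[, 1] >= voi$row_range[1] & idx[, 1] <= voi$row_range[2]))
    expect_true(all(idx[, 2] >= voi$col_range[1] & idx[, 2] <= voi$col_range[2]))
    expect_true(all(idx[, 3] >= voi$first_slice & idx[, 3] <= voi$last_slice))
    expect_identical(voi$first_slice, min(idx[, 3]) - 1L)
    expect_identical(voi$last_slice, max(idx[, 3]) + 1L)
  }
})

test_that("subtraction images are pre/post differences with index validation", {
  case <- tiny_case(100, 150, 200)
  expect_equal(subtraction_image(case, 1), array(50, c(3, 3, 1)))
  expect_equal(subtraction_image(case, 2), array(100, c(3, 3, 1)))
  expect_error(subtraction_image(case, 0), class = "dceseg_index_error")
  expect_error(subtraction_image(case, 3), class = "dceseg_index_error")
})

test_that("lesion subtraction exceeds background subtraction without noise", {
  case <- mass_case(noise = 0)
  sub <- subtraction_image(case, 2)
  expect_gt(min(sub[case$truth_mask]), max(sub[!case$truth_mask]))
})

test_that("second postcontrast subtraction carries more lesion signal than the first", {
  for (case in list(mass_case(seed = 21L), mass_case(seed = 22L, pathology = "benign"))) {
    s1 <- mean(subtraction_image(case, 1)[case$truth_mask])
    s2 <- mean(subtraction_image(case, 2)[case$truth_mask])
    expect_gt(s2, s1)
  }
})

test_that("cohort composition follows largest-remainder allocation", {
  comp <- data.frame(enhancement_type = c("mass", "nonmass"),
                     pathology = c("malignant", "malignant"),
                     prop = c(0.7, 0.3))
  tab <- sample_cohort_table(20, comp, seed = 1L)
  expect_identical(sum(tab$enhancement_type == "mass"), 14L)
  expect_identical(sum(tab$enhancement_type == "nonmass"), 6L)
  expect_false(anyDuplicated(tab$case_id) > 0)

  tab2 <- sample_cohort_table(20, comp, seed = 1L)
  expect_identical(tab, tab2)
})

test_that("the full-scale cohort table reproduces the clinical stratum counts", {
  tab <- sample_cohort_table(994, seed = 3L)
  expect_identical(sum(tab$enhancement_type == "mass"), 687L)
  expect_identical(sum(tab$enhancement_type == "nonmass"), 224L)
  expect_identical(sum(tab$enhancement_type == "unknown"), 83L)
  expect_identical(sum(tab$pathology == "malignant"), 517L + 175L + 32L)
})

test_that("generated cohorts are reproducible and size-consistent", {
  comp <- data.frame(enhancement_type = "mass", pathology = "malignant", prop = 1)
  a <- generate_cohort(3, comp, fixed_protocol(), seed = 5L)
  b <- generate_cohort(3, comp, fixed_protocol(), seed = 5L)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[2]]$series, b$cases[[2]]$series)
  expect_identical(a$manifest$size_bin, size_bin(a$manifest$effective_diameter_mm))
})
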