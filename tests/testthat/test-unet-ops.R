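test_that("range-preserving resize keeps the exact source range", {
  set.seed(20)
  m <- matrix(runif(64 * 48, 0, 812), 64, 48)
  m[1, 1] <- 0; m[2, 2] <- 812
  r <- resize_bilinear(m, 256, 256)
  expect_identical(dim(r), c(256L, 256L))
  expect_equal(range(r), c(0, 812), tolerance = 1e-5)

  expect_identical(resize_bilinear(m, 64, 48), m)          # identity
  const <- matrix(3, 5, 5)
  expect_true(all(resize_bilinear(const, 9, 9) == 3))
  for (i in 1:10) {
    mm <- matrix(rnorm(20 * 30), 20, 30)
    rr <- resize_bilinear(mm, sample(5:50, 1), sample(5:50, 1))
    expect_equal(range(rr), range(mm), tolerance = 1e-5)
  }
})

test_that("2D training sets exclude top/bottom slices only for thick lesions", {
  case5 <- mass_case(d = 10, seed = 31L)          # several VOI slices
  voi <- case5$voi
  ns <- voi$last_slice - voi$first_slice + 1L
  expect_gte(ns, 3L)
  ref <- segmentation_mask(crop_to_voi(case5$truth_mask, voi), voi,
                           case5$spacing_mm)
  samp <- make_2d_training_set(list(case5), list(ref), timepoint = 2L,
                               input_size = 32L)
  expect_identical(length(samp), ns - 2L)
  expect_identical(vapply(samp, function(s) s$slice_index, 0L),
                   2:(ns - 1L))
  expect_false(any(vapply(samp, function(s) s$kept_all_slices, TRUE)))

  # image range preserved by the resize
  sub <- crop_to_voi(subtraction_image(case5, 2L), voi)
  expect_equal(range(samp[[1]]$image), range(sub[, , 2]), tolerance = 1e-5)

  # degenerate 2-slice lesion keeps both slices, flagged
  thin <- case5
  thin$voi$last_slice <- thin$voi$first_slice + 1L
  thin$truth_mask[, , (thin$voi$last_slice + 1L):dim(thin$truth_mask)[3]] <- FALSE
  ref2 <- segmentation_mask(crop_to_voi(thin$truth_mask, thin$voi), thin$voi,
                            thin$spacing_mm)
  samp2 <- make_2d_training_set(list(thin), list(ref2), 2L, 32L)
  expect_identical(length(samp2), 2L)
  expect_true(all(vapply(samp2, function(s) s$kept_all_slices, TRUE)))
})

test_that("3D training samples keep the axial slice count", {
  case <- mass_case(d = 8, seed = 33L)
  ref <- segmentation_mask(crop_to_voi(case$truth_mask, case$voi), case$voi,
                           case$spacing_mm)
  samp <- make_3d_training_set(list(case), list(ref), 2L, 16L)
  ns <- case$voi$last_slice - case$voi$first_slice + 1L
  expect_identical(dim(samp[[1]]$image), c(16L, 16L, ns))
  expect_identical(dim(samp[[1]]$target), c(16L, 16L, ns))
  expect_true(all(samp[[1]]$target %in% c(0, 1)))
})

test_that("prediction covers every VOI slice and requires a trained model", {
  case <- mass_case(d = 8, seed = 34L)
  ns <- case$voi$last_slice - case$voi$first_slice + 1L
  cfg <- unet_config("2d", levels = 2L, base_filters = 2L, input_size = 16L)
  model <- structure(list(params = unet_init_params(cfg, 1L), config = cfg,
                          loss_log = 1), class = "dce_unet")
  maps <- predict_slices(model, case, timepoint = 2L)
  expect_identical(length(maps), as.integer(ns))
  expect_true(all(vapply(maps, function(m) all(m >= 0 & m <= 1), TRUE)))
  maps2 <- predict_slices(model, case, timepoint = 2L)
  expect_identical(maps, maps2)

  untrained <- structure(list(params = NULL, config = cfg), class = "dce_unet")
  expect_error(predict_slices(untrained, case), class = "dceseg_state_error")
  cfg3 <- unet_config("3d", levels = 2L, base_filters = 2L, input_size = 16L)
  model3 <- structure(list(params = unet_init_params(cfg3, 1L), config = cfg3),
                      class = "dce_unet")
  expect_error(predict_slices(model3, case), class = "dceseg_state_error")
  expect_error(predict_3d(model, case), class = "dceseg_state_error")
})

test_that("quasi-3D assembly thresholds and stacks slice maps", {
  cyl <- matrix(0.05, 12, 12); cyl[4:8, 4:8] <- 0.95
  maps <- list(cyl, cyl, cyl)
  m <- assemble_quasi3d(maps, threshold = 0.25)
  expect_identical(dim(m$mask), c(12L, 12L, 3L))
  expect_identical(m$mask[, , 2], cyl > 0.25)
  expect_false(m$failed)

  flat <- assemble_quasi3d(list(matrix(0.1, 6, 6)), threshold = 0.25)
  expect_true(flat$failed)
  expect_false(any(flat$mask))

  single <- assemble_quasi3d(list(cyl), threshold = 0.25)
  expect_identical(single$mask[, , 1], cyl > 0.25)

  expect_error(assemble_quasi3d(maps, threshold = 1.5),
               class = "dceseg_value_error")
  expect_error(assemble_quasi3d(maps, threshold = 0),
               class = "dceseg_value_error")
})

test_that("3D predictions threshold the probability volume and flag failures", {
  case <- mass_case(d = 8, seed = 35L)
  cfg3 <- unet_config("3d", levels = 2L, base_filters = 2L, input_size = 16L)
  model3 <- structure(list(params = unet_init_params(cfg3, 2L), config = cfg3,
                           loss_log = 1), class = "dce_unet")
  seg <- predict_3d(model3, case, timepoint = 2L, threshold = 0.23)
  ns <- case$voi$last_slice - case$voi$first_slice + 1L
  expect_identical(dim(seg$mask), c(16L, 16L, as.integer(ns)))
  prob <- dceseg:::predict_3d_probability(model3, case, timepoint = 2L)
  expect_identical(seg$mask, prob > 0.23)
  expect_identical(seg$failed, !any(prob > 0.23))
  expect_error(predict_3d(model3, case, threshold = 1.5),
               class = "dceseg_value_error")
})

test_that("threshold calibration is an exact grid argmax with smallest-tie-break", {
  ref <- matrix(FALSE, 10, 10); ref[4:7, 4:7] <- TRUE
  ring <- matrix(FALSE, 10, 10); ring[3:8, 3:8] <- TRUE
  prob <- matrix(0.05, 10, 10); prob[ring & !ref] <- 0.2; prob[ref] <- 0.9
  cal <- calibrate_threshold(list(prob), list(ref))
  expect_equal(cal$selected, 0.21)
  expect_equal(max(cal$mean_dsc), 1)

  perfect <- calibrate_threshold(list(ref * 1), list(ref))
  expect_equal(perfect$selected, 0.14)   # all grid values tie at DSC 1

  one <- calibrate_threshold(list(prob), list(ref), grid = 0.25)
  expect_equal(one$selected, 0.25)

  expect_error(calibrate_threshold(list(), list()), class = "dceseg_config_error")
})

test_that("calibration equals brute-force grid evaluation on random maps", {
  set.seed(55)
  grid <- seq(0.14, 0.30, by = 0.01)
  for (rep in 1:10) {
    probs <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
    refs <- lapply(1:4, function(i) random_mask(8, 8))
    cal <- calibrate_threshold(probs, refs, grid)
    brute <- vapply(grid, function(th)
      mean(mapply(function(p, r) dice(p >= th, r), probs, refs)), numeric(1))
    expect_equal(cal$mean_dsc, brute, tolerance = 1e-12)
    expect_identical(cal$selected, grid[which(brute >= max(brute) - 1e-12)[1]])
  }
})

test_that("predictions resize back to the original VOI grid", {
  voi <- lesion_voi(c(1, 64), c(1, 64), 1, 1)
  sp <- c(row = 1, col = 1, slice = 1)
  disk <- matrix(0.04, 64, 64)
  xy <- expand.grid(1:64, 1:64)
  disk[(xy[, 1] - 32)^2 + (xy[, 2] - 32)^2 <= 14^2] <- 0.9
  identity_back <- resize_prediction_to_voi(array(disk, c(64, 64, 1)), voi, sp, 0.25)
  expect_identical(identity_back$mask[, , 1], disk > 0.25)

  voi_small <- lesion_voi(c(1, 16), c(1, 16), 1, 1)
  down <- resize_prediction_to_voi(array(disk, c(64, 64, 1)), voi_small, sp, 0.25)
  expect_identical(max(label_components(down$mask[, , 1], connectivity = 4L)), 1L)

  voi_bad <- lesion_voi(c(1, 16), c(1, 16), 1, 3)
  expect_error(resize_prediction_to_voi(array(disk, c(64, 64, 1)), voi_bad, sp),
               class = "dceseg_integrity_error")
})
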