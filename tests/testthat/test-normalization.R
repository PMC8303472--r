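test_that("post-processing gain is the outside-sector mean, with sanity warning", {
  img <- gray_image(matrix(0L, 20, 20))
  roi <- rect_roi(0, 0, 5, 5)
  expect_equal(estimate_postproc_gain(img, roi), 0)
  img2 <- gray_image(matrix(30L, 20, 20))
  expect_equal(estimate_postproc_gain(img2, roi), 30)
  bright <- gray_image(matrix(200L, 20, 20))
  expect_warning(estimate_postproc_gain(bright, roi), "outside-sector")
})

test_that("gain compensation subtracts with clamping at black", {
  img <- gray_image(matrix(c(100L, 20L, 0L, 255L), 2, 2))
  expect_identical(unclass(compensate_postproc(img, 0)), unclass(img))
  out <- compensate_postproc(img, 30)
  expect_equal(as.vector(out), c(70L, 0L, 0L, 225L))
  expect_error(compensate_postproc(img, 300), "\\[0, 255\\]")
})

test_that("compensation followed by re-estimation yields gain ~ 0", {
  ph <- render_phantom(phantom_scene(seed = 9),
                       acquisition_settings(postproc_gain = 25))
  g <- estimate_postproc_gain(ph$image, ph$rois$outside)
  expect_equal(g, 25, tolerance = 1e-8)
  again <- estimate_postproc_gain(compensate_postproc(ph$image, g), ph$rois$outside)
  expect_lt(again, 0.5)
})

test_that("dark reference is the blood-pool mean and rejects bright ROIs", {
  img <- gray_image(matrix(0L, 10, 10))
  expect_equal(estimate_dark_reference(img, rect_roi(0, 0, 4, 4)), 0)
  quad <- gray_image(matrix(c(10L, 14L, 10L, 14L), 2, 2))
  expect_equal(estimate_dark_reference(quad, rect_roi(0, 0, 2, 2)), 12)
  bright <- gray_image(matrix(180L, 10, 10))
  expect_error(estimate_dark_reference(bright, rect_roi(0, 0, 4, 4)),
               "blood pool")
})

test_that("the phantom dark cavity mean is recovered within noise error", {
  means <- vapply(1:25, function(s) {
    ph <- render_phantom(phantom_scene(seed = s), acquisition_settings())
    estimate_dark_reference(ph$image, ph$rois$dark)
  }, numeric(1))
  # cavity target level is 18; speckle is mean-1 multiplicative
  expect_lt(abs(mean(means) - 18), 0.5)
})

test_that("adaptive threshold adds the dark reference and saturates with error", {
  expect_equal(adaptive_threshold(normalization_context(0, 0, 160)), 160)
  expect_equal(adaptive_threshold(normalization_context(0, 20, 160)), 180)
  expect_error(adaptive_threshold(normalization_context(0, 100, 160)), "saturates")
  darks <- seq(0, 90, by = 10)
  thrs <- vapply(darks, function(d)
    adaptive_threshold(normalization_context(0, d, 160)), numeric(1))
  expect_true(all(diff(thrs) > 0))  # monotone increasing in dark reference
})

test_that("intensity normalization subtracts the dark mean without clamping", {
  expect_equal(normalize_intensity(181, normalization_context(0, 0)), 181)
  expect_equal(normalize_intensity(180, normalization_context(0, 14)), 166)
  expect_warning(v <- normalize_intensity(5, normalization_context(0, 14)),
                 "mis-selected")
  expect_equal(v, -9)
})

test_that("shifting the threshold equals subtracting the dark mean from pixels", {
  # the two descriptions of the normalization -- raise the threshold by the
  # dark mean, or subtract the dark mean from every pixel -- classify pixels
  # identically (shown for integer offsets, where the image shift is lossless;
  # the threshold shift is what the pipeline uses because it needs no rounding)
  set.seed(61)
  img <- random_test_image(30, 30)
  for (d in c(7L, 13L, 22L)) {
    via_threshold <- binarize(img, 160 + d)
    via_image <- binarize(compensate_postproc(img, d), 160)
    expect_identical(unclass(via_threshold), unclass(via_image))
  }
})

test_that("the calcium mask is invariant to additive gain on a noiseless scene", {
  # calcium at 190 so no pixel clips at 255 under the largest gain tested
  scene <- phantom_scene(speckle_shape = Inf, seed = 1,
                         calcium = list(list(center = c(70, 96), semi_row = 10,
                                             semi_col = 12, level = 190)))
  masks <- list(); nmeans <- numeric(0)
  for (g in seq(0, 50, by = 10)) {
    ph <- render_phantom(scene, acquisition_settings(postproc_gain = g))
    rep <- run_pipeline(ph$image, pipeline_config(ph$rois$valve, ph$rois$dark))
    masks[[length(masks) + 1L]] <- rep$mask$coords
    nmeans <- c(nmeans, rep$normalized_mean)
  }
  for (i in 2:length(masks)) expect_identical(masks[[i]], masks[[1]])
  expect_equal(max(nmeans) - min(nmeans), 0)  # constant to machine precision
})

test_that("a lower-variance cavity gives a more stable threshold", {
  # two dark pools: a quiet one and one with 6x speckle variance; across
  # repeated acquisitions the quiet pool's threshold varies less
  scene_of <- function(seed) phantom_scene(
    cavities = list(
      list(center = c(130, 96), semi_row = 26, semi_col = 20, level = 18, noise_mult = 1),
      list(center = c(120, 40), semi_row = 16, semi_col = 12, level = 18, noise_mult = 6)),
    seed = seed)
  thr <- function(ph, roi) 160 + estimate_dark_reference(median_blur(ph$image, 11), roi)
  quiet <- noisy <- numeric(0)
  for (s in 1:12) {
    sc <- scene_of(s)
    ph <- render_phantom(sc, acquisition_settings())
    quiet_roi <- ph$rois$dark
    e2 <- sc$cavities[[2]]
    noisy_roi <- rect_roi(40 - 8, 120 - 11, 17, 23)
    quiet <- c(quiet, thr(ph, quiet_roi))
    noisy <- c(noisy, thr(ph, noisy_roi))
  }
  expect_lt(population_sd(quiet), population_sd(noisy))
})
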