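test_that("histogram equalization follows the cumulative-histogram remap", {
  # constant image: the inclusive cumulative reaches N at the occupied bin
  expect_equal(as.vector(equalize_histogram(gray_image(matrix(37L, 4, 4)))),
               rep(255L, 16))
  # two-pixel [0, 255]: H'(0) = 1 -> round(255/2) = 128, H'(255) = 2 -> 255
  two <- gray_image(matrix(c(0L, 255L), 1, 2))
  expect_equal(as.vector(equalize_histogram(two)), c(128L, 255L))
  # strict variant leaves the top of the range unused
  expect_equal(as.vector(equalize_histogram(two, "strict")), c(0L, 128L))
  expect_equal(as.vector(equalize_histogram(gray_image(matrix(37L, 2, 2)), "strict")),
               rep(0L, 4))
})

test_that("equalization preserves intensity order and linearizes the cdf", {
  set.seed(21)
  for (i in 1:5) {
    img <- gray_image(matrix(pmin(255, pmax(0, round(rnorm(900, 90, 25)))), 30, 30))
    out <- equalize_histogram(img)
    # order preservation: src(p) <= src(q) => out(p) <= out(q)
    o <- order(as.vector(img))
    expect_true(all(diff(as.vector(out)[o]) >= 0))
    cdf_dev <- function(m) {
      H <- cumsum(tabulate(as.vector(m) + 1L, 256L)) / length(m)
      max(abs(H - (1:256) / 256))
    }
    expect_lt(cdf_dev(out), cdf_dev(img))
  }
})

test_that("multi-threshold labelling counts thresholds at or below the pixel", {
  img <- gray_image(matrix(c(0L, 50L, 100L, 200L), 1, 4))
  expect_equal(as.vector(region_label_by_thresholds(img, c(50, 150))),
               c(0L, 1L, 1L, 2L))
  expect_equal(as.vector(region_label_by_thresholds(img, numeric(0))), rep(0L, 4))
  # boundary: a pixel equal to a threshold joins the upper band
  b <- gray_image(matrix(c(99L, 100L), 1, 2))
  expect_equal(as.vector(region_label_by_thresholds(b, 100)), c(0L, 1L))
  expect_error(region_label_by_thresholds(img, c(150, 50)), "ascending")
  expect_error(region_label_by_thresholds(img, c(100, 300)), "\\[0, 255\\]")
})

test_that("median blur matches the brute-force neighbourhood oracle", {
  expect_error(median_blur(gray_image(matrix(0L, 4, 4)), 2), "odd")
  img <- random_test_image(12, 15)
  expect_identical(unclass(median_blur(img, 1)), unclass(img))      # identity
  expect_equal(as.vector(median_blur(gray_image(matrix(200L, 8, 8)), 5)),
               rep(200L, 64))                                       # constant
  spike <- matrix(0L, 3, 3); spike[2, 2] <- 255L
  expect_equal(as.vector(median_blur(gray_image(spike), 3)), rep(0L, 9))
  set.seed(31)
  for (k in c(3L, 5L)) {
    m <- unclass(random_test_image(11, 13))
    expect_identical(unclass(median_blur(gray_image(m), k)),
                     naive_median_blur(m, k))
  }
})

test_that("median blur draws outputs from the local value set", {
  set.seed(32)
  m <- unclass(random_test_image(10, 10))
  out <- unclass(median_blur(gray_image(m), 3))
  for (i in 1:10) {
    for (j in 1:10) {
      nb <- m[max(1, i - 1):min(10, i + 1), max(1, j - 1):min(10, j + 1)]
      expect_true(out[i, j] %in% nb)
    }
  }
})

test_that("binarization uses the strict 'above threshold' convention", {
  expect_equal(as.vector(binarize(gray_image(matrix(100L, 2, 2)), 160)), rep(0L, 4))
  expect_equal(as.vector(binarize(gray_image(matrix(200L, 2, 2)), 160)), rep(255L, 4))
  edge <- gray_image(matrix(c(159L, 160L, 161L), 1, 3))
  expect_equal(as.vector(binarize(edge, 160)), c(0L, 0L, 255L))
  expect_equal(as.vector(binarize(edge, 160, strict = FALSE)), c(0L, 255L, 255L))
  expect_error(binarize(edge, 300), "\\[0, 255\\]")
})

test_that("white count is monotone non-increasing in the threshold", {
  set.seed(41)
  img <- random_test_image(25, 25)
  counts <- vapply(seq(0, 250, by = 10),
                   function(t) sum(binarize(img, t) == 255L), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dilation is extensive, monotone, and grows a pixel into a block", {
  z <- binarize(gray_image(matrix(0L, 5, 5)), 100)
  expect_equal(sum(dilate(z, 3, 1)), 0)                      # empty stays empty
  one <- matrix(0L, 7, 7); one[4, 4] <- 255L
  d1 <- dilate(binarize(gray_image(one), 100), 3, 1)
  expect_equal(which(unclass(d1) == 255L),
               which(outer(1:7, 1:7, function(i, j) abs(i - 4) <= 1 & abs(j - 4) <= 1)))
  m <- binarize(random_test_image(15, 15), 120)
  expect_identical(unclass(dilate(m, 3, 0)), unclass(m))     # 0 iterations
  set.seed(51)
  for (i in 1:5) {
    a <- binarize(random_test_image(12, 12), 140)
    da <- dilate(a, 3, 1)
    expect_true(all(da[a == 255L] == 255L))                  # extensive
    b <- unclass(a); b[b == 0L][1:10] <- 255L                # a subset of b
    db <- dilate(gray_image(b), 3, 1)
    expect_true(all(db[da == 255L] == 255L))                 # monotone
    expect_identical(unclass(da), naive_dilate(unclass(a), 3L, 1L))
  }
})

test_that("CLAHE keeps flat images flat and preserves region ordering", {
  flat <- clahe_enhance(gray_image(matrix(120L, 64, 64)))
  expect_equal(length(unique(as.vector(flat))), 1L)  # spatially constant
  halves <- gray_image(cbind(matrix(60L, 64, 32), matrix(200L, 64, 32)))
  out <- clahe_enhance(halves)
  expect_lt(max(out[, 1:32]), min(out[, 33:64]))
  expect_error(clahe_enhance(gray_image(matrix(0L, 4, 4))), "tile")
})

test_that("dilation recovers blob pixels lost to blurring", {
  ph <- render_phantom(phantom_scene(seed = 5), acquisition_settings())
  blurred <- median_blur(ph$image, 11)
  thr <- 160 + estimate_dark_reference(blurred, ph$rois$dark)
  bin <- binarize(blurred, thr)
  n_plain <- nrow(extract_calcium_mask(bin, ph$rois$valve)$coords)
  n_dilated <- nrow(extract_calcium_mask(dilate(bin, 3, 1), ph$rois$valve)$coords)
  expect_gte(n_dilated, n_plain)
  expect_gt(n_plain, 0)
})
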