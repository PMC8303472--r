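#' Enhancement configuration
#'
#' Bundles the image-conditioning parameters of the pipeline. Defaults are
#' the operating values used throughout: an 11 x 11 median blur to suppress
#' speckle and sampling noise, a base binarization threshold of 160 grey
#' levels (140 reproduces the earlier, more permissive cut-off), and a
#' single pass of 3 x 3 dilation to recover blob pixels eroded by blurring.
#'
#' @param blur_kernel odd integer >= 1; median-blur window side (default 11).
#' @param base_threshold base binarization threshold in grey levels,
#'   \[0, 255\] (default 160). The adaptive threshold adds the dark-reference
#'   mean on top of this.
#' @param dilation_kernel odd integer >= 1; square structuring element side
#'   (default 3).
#' @param dilation_iterations integer >= 0 (default 1).
#' @param clahe_clip positive clip limit for [clahe_enhance()] (default 2).
#' @param clahe_tiles tile-grid size per axis for [clahe_enhance()]
#'   (default 8).
#' @return an object of class `enhance_config`.
#' @export
enhance_config <- function(blur_kernel = 11L, base_threshold = 160,
                           dilation_kernel = 3L, dilation_iterations = 1L,
                           clahe_clip = 2, clahe_tiles = 8L) {
  check_odd <- function(k, what) {
    if (k < 1 || k %% 2 == 0)
      stop(what, " must be an odd integer >= 1", call. = FALSE)
  }
  check_odd(blur_kernel, "blur_kernel")
  check_odd(dilation_kernel, "dilation_kernel")
  if (base_threshold < 0 || base_threshold > 255)
    stop("base_threshold must lie in [0, 255]", call. = FALSE)
  if (dilation_iterations < 0)
    stop("dilation_iterations must be >= 0", call. = FALSE)
  if (clahe_clip <= 0) stop("clahe_clip must be positive", call. = FALSE)
  structure(list(blur_kernel = as.integer(blur_kernel),
                 base_threshold = base_threshold,
                 dilation_kernel = as.integer(dilation_kernel),
                 dilation_iterations = as.integer(dilation_iterations),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles)),
            class = "enhance_config")
}

#' Global histogram equalization
#'
#' Remaps intensities through the normalized cumulative histogram:
#' `out = round(H'(v) / N * 255)` where `H'(i)` is the cumulative count of
#' pixels with intensity `<= i` and `N` the pixel count. With the default
#' inclusive cumulative the brightest occupied bin maps to 255; the strict
#' variant (`cumulative = "strict"`, `H'(i)` counting pixels `< i`) is kept
#' for comparison but leaves the top of the range unused.
#'
#' @param img a [gray_image()].
#' @param cumulative `"inclusive"` (default) or `"strict"`.
#' @return an equalized `gray_image`.
#' @export
equalize_histogram <- function(img, cumulative = c("inclusive", "strict")) {
  img <- gray_image(unclass(img))
  cumulative <- match.arg(cumulative)
  h <- tabulate(as.vector(img) + 1L, nbins = 256L)
  H <- cumsum(h)
  if (cumulative == "strict") H <- c(0L, H[-256L])
  lut <- round_half_away(H / length(img) * 255)
  gray_image(matrix(lut[as.vector(img) + 1L], nrow(img), ncol(img)))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise clipped-histogram equalization with bilinear interpolation
#' between tile mappings, via \pkg{EBImage}. Used here as a visualization
#' aid for inspecting low-contrast studies; it is not a stage of the
#' quantification pipeline, whose segmentation works on absolute
#' intensities.
#'
#' @param img a [gray_image()], at least `clahe_tiles` pixels per side.
#' @param cfg an [enhance_config()] supplying `clahe_clip` and `clahe_tiles`.
#' @return a `gray_image`.
#' @export
clahe_enhance <- function(img, cfg = enhance_config()) {
  img <- gray_image(unclass(img))
  nt <- cfg$clahe_tiles
  if (nrow(img) < nt || ncol(img) < nt)
    stop("image smaller than the CLAHE tile grid", call. = FALSE)
  if (min(img) == max(img)) return(img)  # flat image: nothing to equalize
  out <- EBImage::clahe(unclass(img) / 255, nx = nt, ny = nt,
                        limit = cfg$clahe_clip, keep.range = TRUE)
  out <- pmin(pmax(as.matrix(out), 0), 1)
  gray_image(matrix(round_half_away(out * 255), nrow(img), ncol(img)))
}

#' Multi-threshold region labelling
#'
#' Segments the image into intensity bands: a pixel with value `v` receives
#' label `k`, the number of thresholds `t` with `t <= v`. Label 0 is the
#' background below the first threshold; a pixel equal to a threshold joins
#' the upper band.
#'
#' @param img a [gray_image()].
#' @param thresholds strictly ascending numeric vector in \[0, 255\]
#'   (possibly empty).
#' @return an integer matrix of labels `0..length(thresholds)`.
#' @export
region_label_by_thresholds <- function(img, thresholds) {
  img <- gray_image(unclass(img))
  if (length(thresholds)) {
    if (any(thresholds < 0) || any(thresholds > 255))
      stop("thresholds must lie in [0, 255]", call. = FALSE)
    if (is.unsorted(thresholds, strictly = TRUE))
      stop("thresholds must be strictly ascending", call. = FALSE)
  }
  lab <- matrix(0L, nrow(img), ncol(img))
  for (t in thresholds) lab <- lab + (unclass(img) >= t)
  lab
}

#' Median blur
#'
#' Replaces each pixel by the median of its `k` x `k` neighbourhood
#' (replicate border padding), the pipeline's noise-suppression stage.
#' Because `k*k` is odd, the output only contains values present in the
#' corresponding input neighbourhood.
#'
#' @param img a [gray_image()].
#' @param k odd window side, >= 1.
#' @return a blurred `gray_image`.
#' @export
median_blur <- function(img, k) {
  img <- gray_image(unclass(img))
  if (k < 1 || k %% 2 == 0) stop("'k' must be an odd integer >= 1", call. = FALSE)
  if (k == 1L) return(img)
  gray_image(.median_filter_cpp(unclass(img), as.integer(k)))
}

#' Fixed-threshold binarization
#'
#' Pixels with intensity strictly above the threshold become white (255),
#' all others black (0). Set `strict = FALSE` for an inclusive `>=`
#' comparison.
#'
#' @param img a [gray_image()].
#' @param threshold cut-off in grey levels, \[0, 255\] (need not be integer:
#'   the adaptive threshold is base + a real-valued dark mean).
#' @param strict logical; compare with `>` (default) or `>=`.
#' @return a `binary_image`.
#' @export
binarize <- function(img, threshold, strict = TRUE) {
  img <- gray_image(unclass(img))
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  keep <- if (strict) unclass(img) > threshold else unclass(img) >= threshold
  as_binary_image(matrix(255L * keep, nrow(img), ncol(img)))
}

#' Binary dilation
#'
#' Morphological dilation with a square structuring element, used after
#' blur + binarization to recover calcium pixels eroded at blob boundaries
#' by the median filter. Extensive (output white set contains the input's)
#' and monotone in the input mask.
#'
#' @param mask a `binary_image` (from [binarize()]).
#' @param kernel odd structuring-element side, >= 1.
#' @param iterations number of dilation passes, >= 0 (0 is the identity).
#' @return a `binary_image`.
#' @export
dilate <- function(mask, kernel = 3L, iterations = 1L) {
  mask <- as_binary_image(unclass(mask))
  if (kernel < 1 || kernel %% 2 == 0)
    stop("'kernel' must be an odd integer >= 1", call. = FALSE)
  if (iterations < 0) stop("'iterations' must be >= 0", call. = FALSE)
  if (iterations == 0L || kernel == 1L) return(mask)
  as_binary_image(.dilate_cpp(unclass(mask), as.integer(kernel),
                              as.integer(iterations)))
}

#' 8-connected components of a binary image
#'
#' @param mask a `binary_image`.
#' @return an integer label matrix (0 = background, components numbered from 1).
#' @export
label_components <- function(mask) {
  mask <- as_binary_image(unclass(mask))
  .label8_cpp(unclass(mask))
}
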