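#' @useDynLib echocalc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Round to nearest integer, halves away from zero. Used everywhere an
# integer image is produced; base round() rounds halves to even.
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Grayscale image
#'
#' The pipeline's universal currency: a matrix of 8-bit intensities in
#' \[0, 255\], indexed \[row, col\]. Binary images (values 0/255 only) are the
#' subclass produced by [binarize()] and consumed by mask extraction.
#'
#' @param x numeric matrix with all values in \[0, 255\]. Values must be
#'   whole numbers; storage mode is coerced to integer.
#' @return an integer matrix of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:249, 25, 10))
#' dim(img)
#' @export
gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(x)) stop("image contains missing values", call. = FALSE)
  if (any(x < 0) || any(x > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (any(x != trunc(x)))
    stop("intensities must be whole numbers; quantize first", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = c("gray_image", class(matrix())))
}

is_binary <- function(img) all(img == 0L | img == 255L)

as_binary_image <- function(x) {
  img <- gray_image(x)
  if (!is_binary(img)) stop("binary image must contain only 0 and 255", call. = FALSE)
  class(img) <- c("binary_image", class(img))
  img
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<%s> %d x %d, intensity range [%d, %d]\n",
              class(x)[1L], nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Axis-aligned rectangle in 0-based, half-open coordinates: it covers
#' columns `[x0, x0 + width)` and rows `[y0, y0 + height)`. ROIs select the
#' aortic valve, the dark blood-pool reference (typically the left atrium
#' cavity) and the outside-sector background patch.
#'
#' @param x0,y0 0-based column/row of the top-left corner.
#' @param width,height extent in pixels, both >= 1.
#' @return an object of class `rect_roi`.
#' @examples
#' rect_roi(10, 20, 32, 16)
#' @export
rect_roi <- function(x0, y0, width, height) {
  vals <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (anyNA(vals) || any(vals != trunc(vals)))
    stop("ROI fields must be whole numbers", call. = FALSE)
  if (x0 < 0 || y0 < 0) stop("ROI origin must be non-negative", call. = FALSE)
  if (width < 1 || height < 1) stop("ROI width and height must be >= 1", call. = FALSE)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> x0=%d y0=%d width=%d height=%d\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

assert_roi_inside <- function(img, roi, what = "ROI") {
  stopifnot(inherits(roi, "rect_roi"))
  if (roi$y0 + roi$height > nrow(img) || roi$x0 + roi$width > ncol(img))
    stop(sprintf("%s extends outside the %d x %d image", what, nrow(img), ncol(img)),
         call. = FALSE)
  invisible(TRUE)
}

# 1-based row/col index vectors of a ROI.
roi_rows <- function(roi) seq.int(roi$y0 + 1L, roi$y0 + roi$height)
roi_cols <- function(roi) seq.int(roi$x0 + 1L, roi$x0 + roi$width)

#' Crop an image to a ROI
#'
#' @param img a [gray_image()] (or plain intensity matrix).
#' @param roi a [rect_roi()] lying entirely inside `img`.
#' @return a `gray_image` of size `roi$height` x `roi$width`.
#' @export
crop <- function(img, roi) {
  img <- gray_image(unclass(img))
  assert_roi_inside(img, roi)
  gray_image(unclass(img)[roi_rows(roi), roi_cols(roi), drop = FALSE])
}

#' Mean intensity inside a ROI
#'
#' The primitive behind both normalization references: the outside-sector
#' mean (post-processing gain) and the blood-pool mean (the "black
#' threshold" offset).
#'
#' @inheritParams crop
#' @return the unrounded arithmetic mean, a real number in \[0, 255\].
#' @export
roi_mean <- function(img, roi) {
  img <- gray_image(unclass(img))
  assert_roi_inside(img, roi)
  mean(unclass(img)[roi_rows(roi), roi_cols(roi)])
}

#' Window width / window level display mapping
#'
#' `windowing_params()` holds the linear grey-scale display mapping used in
#' ultrasound post-processing: intensities across a window of width `ww`
#' centred at level `wl` are stretched linearly onto \[0, 255\], and values
#' outside the window clamp to 0 or 255. `apply_windowing()` applies it:
#' `display = clamp((raw - (wl - ww/2)) / ww, 0, 1) * 255`, rounded to the
#' nearest integer (halves away from zero). `identity_windowing()`
#' (`ww = 255`, `wl = 127.5`) maps 8-bit input onto itself.
#'
#' @param ww window width in grey levels, > 0.
#' @param wl window level (window centre) in grey levels.
#' @return `windowing_params()` returns a parameter object;
#'   `apply_windowing()` returns a `gray_image`.
#' @examples
#' wp <- windowing_params(250, 100)
#' apply_windowing(matrix(100, 1, 1), wp)  # mid-window -> 128
#' @export
windowing_params <- function(ww, wl) {
  if (!is.numeric(ww) || length(ww) != 1L || ww <= 0)
    stop("window width must be a positive number", call. = FALSE)
  if (!is.numeric(wl) || length(wl) != 1L)
    stop("window level must be a single number", call. = FALSE)
  structure(list(ww = ww, wl = wl), class = "windowing_params")
}

#' @rdname windowing_params
#' @export
identity_windowing <- function() windowing_params(255, 127.5)

#' @rdname windowing_params
#' @param raw numeric matrix of raw intensities (any real values; the raw
#'   acquisition domain is not restricted to 8 bits).
#' @param wp a [windowing_params()] object.
#' @export
apply_windowing <- function(raw, wp) {
  stopifnot(inherits(wp, "windowing_params"))
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix", call. = FALSE)
  u <- (raw - (wp$wl - wp$ww / 2)) / wp$ww
  u <- pmin(pmax(u, 0), 1)
  gray_image(matrix(round_half_away(u * 255), nrow(raw), ncol(raw)))
}

#' Load an image file as 8-bit grayscale
#'
#' Reads a PNG or TIFF file and returns intensities scaled to \[0, 255\].
#' Color inputs are converted to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is ignored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [gray_image()].
#' @export
load_grayscale <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG/TIFF supported)", call. = FALSE)
  )
  if (length(arr) == 0L) stop("zero-sized image: ", path, call. = FALSE)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    y <- if (nch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]  # grayscale(+alpha) stored as planes
    }
    y <- matrix(y, dim(arr)[1L], dim(arr)[2L])
  } else {
    y <- arr
  }
  gray_image(matrix(round_half_away(y * 255), nrow(y), ncol(y)))
}

#' Write a grayscale image to PNG
#'
#' @param img a [gray_image()] or binary image.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_grayscale <- function(img, path) {
  img <- gray_image(unclass(img))
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}
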