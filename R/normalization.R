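#' Normalization context
#'
#' Carries the two brightness references that make the binarization
#' adaptive: the post-processing gain (mean of a region outside the
#' ultrasound sector — brightness added after acquisition) and the dark
#' reference (mean of a blood-pool region inside the sector, the "black
#' threshold"), together with the base binarization threshold they adjust.
#'
#' @param postproc_gain outside-sector mean, in \[0, 255\] (default 0).
#' @param dark_reference dark blood-pool mean, in \[0, 255\] (default 0).
#' @param base_threshold base threshold in grey levels (default 160).
#' @return an object of class `normalization_context`.
#' @seealso [adaptive_threshold()], [run_pipeline()]
#' @export
normalization_context <- function(postproc_gain = 0, dark_reference = 0,
                                  base_threshold = 160) {
  for (v in c(postproc_gain, dark_reference))
    if (v < 0 || v > 255) stop("offsets must lie in [0, 255]", call. = FALSE)
  if (base_threshold < 0 || base_threshold > 255)
    stop("base_threshold must lie in [0, 255]", call. = FALSE)
  structure(list(postproc_gain = postproc_gain,
                 dark_reference = dark_reference,
                 base_threshold = base_threshold),
            class = "normalization_context")
}

#' @export
print.normalization_context <- function(x, ...) {
  cat(sprintf(paste0("<normalization_context> gain=%.2f dark=%.2f base=%g",
                     " -> threshold=%.2f\n"),
              x$postproc_gain, x$dark_reference, x$base_threshold,
              adaptive_threshold(x)))
  invisible(x)
}

#' Estimate the post-processing gain
#'
#' Mean intensity of a region outside the ultrasound sector. That area
#' receives no echo signal, so any brightness there was added by display
#' post-processing (window/level mapping, extra gains) and can be
#' subtracted to recover the acquired image. A warning is raised when the
#' estimate exceeds 128 — a region that bright is unlikely to lie outside
#' the sector.
#'
#' @param img a [gray_image()].
#' @param outside_roi a [rect_roi()] placed outside the imaging sector.
#' @return the gain estimate, a real number in \[0, 255\].
#' @export
estimate_postproc_gain <- function(img, outside_roi) {
  g <- roi_mean(img, outside_roi)
  if (g > 128)
    warning(sprintf(paste0("outside-sector ROI mean is %.1f (> 128); the ROI",
                           " probably overlaps the imaging sector"), g),
            call. = FALSE)
  g
}

#' Subtract the post-processing gain from an image
#'
#' `pixel -> max(0, round(pixel - gain))`, restoring (up to clamping at
#' black) the image as acquired before display post-processing.
#'
#' @param img a [gray_image()].
#' @param gain real offset in \[0, 255\], typically from
#'   [estimate_postproc_gain()].
#' @return a gain-compensated `gray_image`.
#' @export
compensate_postproc <- function(img, gain) {
  img <- gray_image(unclass(img))
  if (gain < 0 || gain > 255) stop("gain must lie in [0, 255]", call. = FALSE)
  v <- pmax(round_half_away(unclass(img) - gain), 0L)
  gray_image(matrix(as.integer(v), nrow(img), ncol(img)))
}

#' Estimate the dark reference ("black threshold")
#'
#' Mean intensity of a dark blood-pool region inside the sector — by
#' convention the left atrium cavity, whose blood should be nearly black
#' under any acquisition settings. This mean captures the brightness the
#' current settings add to every structure and is what shifts the
#' binarization threshold per image. An error is raised when the region
#' mean exceeds the base threshold: a "dark" reference brighter than the
#' calcium cut-off means the ROI was mis-placed (nothing could be
#' classified as calcium once the threshold saturates).
#'
#' @param img the [gray_image()] actually thresholded (in the pipeline:
#'   blurred and gain-compensated).
#' @param dark_roi a [rect_roi()] on a blood pool.
#' @param base_threshold the base threshold the estimate will be added to
#'   (default 160), used only for the mis-selection check.
#' @return the dark-reference mean, a real number in \[0, 255\].
#' @export
estimate_dark_reference <- function(img, dark_roi, base_threshold = 160) {
  d <- roi_mean(img, dark_roi)
  if (d > base_threshold)
    stop(sprintf(paste0("dark-reference ROI mean (%.1f) exceeds the base",
                        " threshold (%g); select the ROI on a blood pool"),
                 d, base_threshold), call. = FALSE)
  d
}

#' Adaptive binarization threshold
#'
#' `base_threshold + dark_reference`: the fixed calcium cut-off shifted by
#' the measured per-image brightness offset, giving a dynamic threshold
#' that follows acquisition-setting changes. Errors if the sum reaches 255,
#' since a saturated threshold can never classify any pixel as calcium.
#'
#' @param ctx a [normalization_context()].
#' @return the effective threshold in grey levels (real-valued).
#' @export
adaptive_threshold <- function(ctx) {
  stopifnot(inherits(ctx, "normalization_context"))
  thr <- ctx$base_threshold + ctx$dark_reference
  if (thr >= 255)
    stop(sprintf(paste0("adaptive threshold saturates (base %g + dark %.1f",
                        " >= 255); no pixel could be calcium -- check the",
                        " dark-reference ROI"),
                 ctx$base_threshold, ctx$dark_reference), call. = FALSE)
  thr
}

#' Normalize an intensity against the dark reference
#'
#' `value - dark_reference`, the scale on which calcium intensities are
#' reported so that studies acquired under different settings are
#' comparable. Not clamped: calcium pixels exceed the dark mean by
#' construction, and a negative result (which triggers a warning) signals a
#' mis-selected ROI rather than a value to hide.
#'
#' @param value intensity (or vector of intensities) in \[0, 255\].
#' @param ctx a [normalization_context()].
#' @return the normalized intensity (real, possibly unrounded).
#' @export
normalize_intensity <- function(value, ctx) {
  stopifnot(inherits(ctx, "normalization_context"))
  if (any(value < 0) || any(value > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  out <- value - ctx$dark_reference
  if (any(out < 0))
    warning("normalized intensity below zero; the dark-reference ROI may be mis-selected",
            call. = FALSE)
  out
}
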