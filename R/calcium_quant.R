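#' Calcium mask
#'
#' The set of pixels classified as calcium inside the valve ROI, stored as
#' 0-based `(row, col)` image coordinates in row-major order.
#'
#' @param binary a `binary_image` (adaptive-thresholded, optionally dilated).
#' @param roi the valve [rect_roi()].
#' @return an object of class `calcium_mask` with fields `roi` and `coords`
#'   (n x 2 integer matrix, columns `row`, `col`).
#' @export
extract_calcium_mask <- function(binary, roi) {
  binary <- as_binary_image(unclass(binary))
  assert_roi_inside(binary, roi, "valve ROI")
  sub <- unclass(binary)[roi_rows(roi), roi_cols(roi), drop = FALSE]
  idx <- which(t(sub) == 255L)  # transpose -> row-major enumeration
  n <- length(idx)
  coords <- cbind(row = roi$y0 + (idx - 1L) %/% roi$width,
                  col = roi$x0 + (idx - 1L) %% roi$width)
  storage.mode(coords) <- "integer"
  structure(list(roi = roi, coords = coords), class = "calcium_mask")
}

#' @export
print.calcium_mask <- function(x, ...) {
  cat(sprintf("<calcium_mask> %d white pixel(s) in %dx%d ROI at (%d,%d)\n",
              nrow(x$coords), x$roi$width, x$roi$height, x$roi$x0, x$roi$y0))
  invisible(x)
}

#' Quantify calcium under a mask
#'
#' The score: the white-pixel count (a proxy of calcium area) plus raw and
#' dark-normalized intensity statistics taken from `original` — the
#' unblurred (gain-compensated) image — at the mask coordinates. Blurring
#' only drives detection; reported intensities come from the image as
#' acquired. An empty mask yields count 0 with absent (`NA`) statistics.
#'
#' @param original the [gray_image()] supplying intensities.
#' @param mask a [extract_calcium_mask()] result.
#' @param ctx the [normalization_context()] of the run.
#' @param components optional integer vector of per-component white-pixel
#'   counts (see [run_pipeline()]).
#' @return an object of class `calcium_report` with fields
#'   `white_pixel_count`, `raw_mean`, `raw_median`, `normalized_mean`,
#'   `normalized_median`, `effective_threshold`, `context`,
#'   `component_counts`.
#' @export
quantify <- function(original, mask, ctx, components = NULL) {
  original <- gray_image(unclass(original))
  stopifnot(inherits(mask, "calcium_mask"),
            inherits(ctx, "normalization_context"))
  co <- mask$coords
  if (nrow(co) && (max(co[, "row"]) >= nrow(original) ||
                   max(co[, "col"]) >= ncol(original)))
    stop("mask coordinates fall outside the image", call. = FALSE)
  if (nrow(co)) {
    vals <- unclass(original)[cbind(co[, "row"] + 1L, co[, "col"] + 1L)]
    raw_mean <- mean(vals)
    raw_median <- stats::median(vals)
    norm_mean <- normalize_intensity(raw_mean, ctx)
    norm_median <- normalize_intensity(raw_median, ctx)
  } else {
    raw_mean <- raw_median <- norm_mean <- norm_median <- NA_real_
  }
  structure(list(white_pixel_count = nrow(co),
                 raw_mean = raw_mean, raw_median = raw_median,
                 normalized_mean = norm_mean, normalized_median = norm_median,
                 effective_threshold = adaptive_threshold(ctx),
                 context = ctx,
                 component_counts = components,
                 mask = mask),
            class = "calcium_report")
}

#' @export
print.calcium_report <- function(x, ...) {
  cat("<calcium_report>\n")
  cat(sprintf("  white pixels      : %d\n", x$white_pixel_count))
  if (x$white_pixel_count > 0) {
    cat(sprintf("  raw mean / median : %.2f / %.1f\n", x$raw_mean, x$raw_median))
    cat(sprintf("  norm mean / median: %.2f / %.2f\n",
                x$normalized_mean, x$normalized_median))
  }
  cat(sprintf("  threshold (base %g + dark %.2f): %.2f\n",
              x$context$base_threshold, x$context$dark_reference,
              x$effective_threshold))
  if (!is.null(x$component_counts) && length(x$component_counts))
    cat("  components        :", paste(x$component_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' ROIs and switches for one [run_pipeline()] call. The valve ROI bounds
#' the structure to score; the dark ROI sits on a blood pool (left atrium
#' cavity) and drives the adaptive threshold; the optional outside-sector
#' ROI enables compensation of post-processing gains before anything else
#' runs.
#'
#' @param valve_roi,dark_roi [rect_roi()] objects (required).
#' @param outside_roi optional outside-sector [rect_roi()].
#' @param enhance an [enhance_config()].
#' @param compensate_gain logical; subtract the outside-sector mean first
#'   (default: `TRUE` when `outside_roi` is given).
#' @param apply_dilation logical; dilate the binary image before mask
#'   extraction (default `TRUE`).
#' @param debug_dir optional directory; when set, every intermediate stage
#'   is written there as PNG.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(valve_roi, dark_roi, outside_roi = NULL,
                            enhance = enhance_config(),
                            compensate_gain = !is.null(outside_roi),
                            apply_dilation = TRUE, debug_dir = NULL) {
  stopifnot(inherits(valve_roi, "rect_roi"), inherits(dark_roi, "rect_roi"),
            inherits(enhance, "enhance_config"))
  if (compensate_gain && is.null(outside_roi))
    stop("gain compensation requires an outside-sector ROI", call. = FALSE)
  structure(list(valve_roi = valve_roi, dark_roi = dark_roi,
                 outside_roi = outside_roi, enhance = enhance,
                 compensate_gain = isTRUE(compensate_gain),
                 apply_dilation = isTRUE(apply_dilation),
                 debug_dir = debug_dir),
            class = "pipeline_config")
}

#' Run the full calcium-quantification pipeline
#'
#' Executes the stages in order: (1) optional post-processing gain
#' compensation from the outside-sector ROI; (2) median blur; (3) dark
#' reference estimation on the blurred, compensated image (the image
#' actually thresholded); (4) binarization at the adaptive threshold
#' (base + dark reference); (5) optional dilation; (6) white-pixel mask
#' extraction inside the valve ROI; (7) quantification against the
#' unblurred compensated image. Disconnected calcium areas inside the valve
#' ROI are pooled into the count; their 8-connected per-component counts
#' are reported alongside.
#'
#' @param img input [gray_image()].
#' @param cfg a [pipeline_config()].
#' @return a [quantify()] report carrying the full normalization context.
#' @examples
#' ph <- render_phantom(phantom_scene(seed = 7), acquisition_settings())
#' run_pipeline(ph$image, pipeline_config(ph$rois$valve, ph$rois$dark))
#' @export
run_pipeline <- function(img, cfg) {
  img <- gray_image(unclass(img))
  stopifnot(inherits(cfg, "pipeline_config"))
  assert_roi_inside(img, cfg$valve_roi, "valve ROI")
  assert_roi_inside(img, cfg$dark_roi, "dark-reference ROI")
  dump <- function(stage, im) {
    if (!is.null(cfg$debug_dir)) {
      dir.create(cfg$debug_dir, showWarnings = FALSE, recursive = TRUE)
      write_grayscale(im, file.path(cfg$debug_dir, paste0(stage, ".png")))
    }
  }
  dump("01_input", img)

  gain <- 0
  work <- img
  if (cfg$compensate_gain) {
    assert_roi_inside(img, cfg$outside_roi, "outside-sector ROI")
    gain <- estimate_postproc_gain(img, cfg$outside_roi)
    work <- compensate_postproc(img, gain)
    dump("02_gain_compensated", work)
  }

  blurred <- median_blur(work, cfg$enhance$blur_kernel)
  dump("03_blurred", blurred)

  dark <- estimate_dark_reference(blurred, cfg$dark_roi,
                                  cfg$enhance$base_threshold)
  ctx <- normalization_context(postproc_gain = gain, dark_reference = dark,
                               base_threshold = cfg$enhance$base_threshold)
  bin <- binarize(blurred, adaptive_threshold(ctx))
  dump("04_binarized", bin)

  if (cfg$apply_dilation) {
    bin <- dilate(bin, cfg$enhance$dilation_kernel,
                  cfg$enhance$dilation_iterations)
    dump("05_dilated", bin)
  }

  mask <- extract_calcium_mask(bin, cfg$valve_roi)
  comp <- component_counts(bin, cfg$valve_roi)
  quantify(work, mask, ctx, components = comp)
}

# Per-component white-pixel counts (8-connectivity) inside a ROI.
component_counts <- function(binary, roi) {
  sub <- unclass(binary)[roi_rows(roi), roi_cols(roi), drop = FALSE]
  lab <- .label8_cpp(sub)
  if (max(lab) == 0L) return(integer(0))
  as.integer(tabulate(lab[lab > 0L]))
}

#' Write calcium reports as CSV / JSON
#'
#' One CSV row per image: id, white-pixel count, raw and normalized mean
#' and median, effective threshold, gain and dark reference. The JSON
#' variant additionally echoes per-component counts.
#'
#' @param reports a named list of `calcium_report` objects (names are image
#'   ids).
#' @param path output file path (`.csv` or `.json` decides the format).
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  if (inherits(reports, "calcium_report")) reports <- list(image = reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "calcium_report")))
  if (is.null(names(reports)))
    names(reports) <- sprintf("image_%02d", seq_along(reports))
  rows <- lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(id = id, white_pixels = r$white_pixel_count,
               raw_mean = r$raw_mean, raw_median = r$raw_median,
               normalized_mean = r$normalized_mean,
               normalized_median = r$normalized_median,
               threshold = r$effective_threshold,
               postproc_gain = r$context$postproc_gain,
               dark_reference = r$context$dark_reference)
  })
  df <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- lapply(names(reports), function(id) {
      r <- reports[[id]]
      list(id = id, white_pixels = r$white_pixel_count,
           raw_mean = r$raw_mean, raw_median = r$raw_median,
           normalized_mean = r$normalized_mean,
           normalized_median = r$normalized_median,
           threshold = r$effective_threshold,
           context = unclass(r$context),
           component_counts = r$component_counts)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
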