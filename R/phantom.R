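#' Synthetic echocardiography phantom scene
#'
#' Describes a sector-scan-like test image with exact ground truth: a
#' fan-shaped imaging region (annular wedge, apex at top centre) filled
#' with speckle-textured tissue, dark elliptical blood pools (cavity
#' analogues of the left atrium), and bright elliptical calcium blobs whose
#' pixel sets are known exactly before any noise is applied. Intensities
#' are "raw" acquisition levels; they only become an 8-bit image through
#' the acquisition transform of [render_phantom()].
#'
#' Ellipses are given as `list(center = c(row, col), semi_row, semi_col,
#' level)`; cavities additionally accept `noise_mult` (> 1 for a
#' higher-variance pool, e.g. a right-ventricle analogue with refractions).
#'
#' @param height,width canvas size in pixels.
#' @param sector `list(apex = c(row, col), radius, inner_radius,
#'   half_angle_deg)`; the wedge opens downwards from the apex.
#' @param tissue_level baseline myocardium intensity (default 80).
#' @param cavities list of dark ellipses (default: one blood pool at
#'   level 18).
#' @param calcium list of bright ellipses (default: one blob at level 220).
#' @param speckle_shape shape `k` of the multiplicative Gamma(k, k) speckle
#'   (mean 1, SD `1/sqrt(k)`); default 60 (~13% SD, coarse clinical-like
#'   texture). `Inf` renders a speckle-free scene.
#' @param seed RNG seed owning the speckle realization; renders of one
#'   scene share it unless the acquisition supplies its own.
#' @return an object of class `phantom_scene`.
#' @seealso [render_phantom()], [windowing_study_scene()]
#' @export
phantom_scene <- function(height = 192L, width = 192L,
                          sector = list(apex = c(6, width / 2), radius = 0.9 * height,
                                        inner_radius = 10, half_angle_deg = 37.5),
                          tissue_level = 80,
                          cavities = list(list(center = c(130, width / 2),
                                               semi_row = 26, semi_col = 20,
                                               level = 18, noise_mult = 1)),
                          calcium = list(list(center = c(70, width / 2),
                                              semi_row = 10, semi_col = 12,
                                              level = 220)),
                          speckle_shape = 60, seed = 1L) {
  if (height < 32 || width < 32) stop("canvas must be at least 32 x 32", call. = FALSE)
  if (tissue_level < 0 || tissue_level > 255)
    stop("tissue_level must lie in [0, 255]", call. = FALSE)
  if (speckle_shape <= 0) stop("speckle_shape must be positive", call. = FALSE)
  scene <- structure(list(height = as.integer(height), width = as.integer(width),
                          sector = sector, tissue_level = tissue_level,
                          cavities = cavities, calcium = calcium,
                          speckle_shape = speckle_shape, seed = as.integer(seed)),
                     class = "phantom_scene")
  sec <- sector_mask(scene)
  for (e in c(cavities, calcium)) {
    m <- ellipse_mask(scene, e)
    if (!any(m)) stop("an ellipse rasterizes to zero pixels", call. = FALSE)
    if (any(m & !sec))
      stop("cavity/calcium ellipse extends outside the imaging sector", call. = FALSE)
  }
  scene
}

#' Acquisition transform settings
#'
#' The forward model applied to a scene: multiplicative speckle inside the
#' sector, a power-law contrast compression (analogue of vendor image
#' compression), an additive post-processing gain over the whole canvas,
#' and the window-width/level display mapping that quantizes to 8 bits.
#'
#' @param postproc_gain additive brightness offset, >= 0 (default 0).
#' @param windowing a [windowing_params()]; default [identity_windowing()].
#' @param compression power-law exponent on intensity / 255, > 0
#'   (default 1 = none).
#' @param noise_scale speckle-variance multiplier, > 0; < 1 emulates a
#'   higher ultrasound frequency (finer, weaker speckle). Default 1.
#' @param seed optional per-acquisition RNG seed; when `NULL` (default) the
#'   scene's seed is used, so re-rendering one scene under different
#'   post-processing reuses the same speckle realization — the synthetic
#'   counterpart of re-windowing one stored acquisition.
#' @return an object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(postproc_gain = 0,
                                 windowing = identity_windowing(),
                                 compression = 1, noise_scale = 1,
                                 seed = NULL) {
  if (postproc_gain < 0) stop("postproc_gain must be >= 0", call. = FALSE)
  if (compression <= 0) stop("compression exponent must be > 0", call. = FALSE)
  if (noise_scale <= 0) stop("noise_scale must be > 0", call. = FALSE)
  stopifnot(inherits(windowing, "windowing_params"))
  structure(list(postproc_gain = postproc_gain, windowing = windowing,
                 compression = compression, noise_scale = noise_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "acquisition_settings")
}

# Logical mask of the annular imaging wedge.
sector_mask <- function(scene) {
  s <- scene$sector
  rr <- matrix(seq_len(scene$height), scene$height, scene$width)
  cc <- matrix(seq_len(scene$width), scene$height, scene$width, byrow = TRUE)
  dy <- rr - s$apex[1]
  dx <- cc - s$apex[2]
  d <- sqrt(dy^2 + dx^2)
  ang <- abs(atan2(dx, pmax(dy, 1e-9))) * 180 / pi  # 0 = straight down
  d >= s$inner_radius & d <= s$radius & ang <= s$half_angle_deg & dy > 0
}

# Logical mask of one ellipse (pixel centres).
ellipse_mask <- function(scene, e) {
  rr <- matrix(seq_len(scene$height), scene$height, scene$width)
  cc <- matrix(seq_len(scene$width), scene$height, scene$width, byrow = TRUE)
  ((rr - e$center[1]) / e$semi_row)^2 + ((cc - e$center[2]) / e$semi_col)^2 <= 1
}

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Render a phantom scene through an acquisition transform
#'
#' Raster order: rasterize regions (sector tissue, cavities, calcium) ->
#' multiplicative Gamma speckle inside the sector only -> power-law
#' compression -> additive post-processing gain everywhere (so the
#' outside-sector background is exactly the gain before windowing) ->
#' window/level mapping with quantization to \[0, 255\]. Deterministic for
#' a fixed seed.
#'
#' @param scene a [phantom_scene()].
#' @param acq an [acquisition_settings()].
#' @return an object of class `phantom_render`: `image` (the
#'   [gray_image()]), `truth` (exact pre-noise calcium pixel mask, total
#'   and per-blob counts), `true_normalized` (per-blob raw calcium level
#'   minus the first cavity's level — the target of dark-reference
#'   normalization), suggested `rois` (`valve`, `dark`, `outside`), and the
#'   generating `scene`/`acq`.
#' @examples
#' ph <- render_phantom(phantom_scene(seed = 3),
#'                      acquisition_settings(postproc_gain = 20))
#' ph$truth$count
#' @export
render_phantom <- function(scene, acq = acquisition_settings()) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(acq, "acquisition_settings"))
  sec <- sector_mask(scene)
  base <- matrix(0, scene$height, scene$width)
  base[sec] <- scene$tissue_level
  cav_masks <- lapply(scene$cavities, function(e) ellipse_mask(scene, e))
  for (i in seq_along(scene$cavities)) base[cav_masks[[i]]] <- scene$cavities[[i]]$level
  cal_masks <- lapply(scene$calcium, function(e) ellipse_mask(scene, e))
  for (i in seq_along(scene$calcium)) base[cal_masks[[i]]] <- scene$calcium[[i]]$level

  seed <- if (is.null(acq$seed)) scene$seed else acq$seed
  raw <- with_seed(seed, {
    k <- scene$speckle_shape / acq$noise_scale
    s <- if (is.finite(k)) {
      matrix(stats::rgamma(length(base), shape = k, rate = k),
             scene$height, scene$width)
    } else {
      matrix(1, scene$height, scene$width)  # speckle-free scene
    }
    if (is.finite(k)) {
      for (i in seq_along(scene$cavities)) {
        nm <- scene$cavities[[i]]$noise_mult
        if (!is.null(nm) && nm != 1) {
          idx <- which(cav_masks[[i]])
          s[idx] <- stats::rgamma(length(idx), shape = k / nm, rate = k / nm)
        }
      }
    }
    out <- base
    out[sec] <- out[sec] * s[sec]
    out
  })
  if (acq$compression != 1) raw <- 255 * (raw / 255)^acq$compression
  raw <- raw + acq$postproc_gain
  img <- apply_windowing(raw, acq$windowing)

  valve <- blob_bbox_roi(scene, cal_masks)
  truth_union <- Reduce(`|`, cal_masks)
  mask <- mask_from_logical(truth_union, valve)
  dark_ref_level <- scene$cavities[[1]]$level
  structure(list(
    image = img,
    truth = list(mask = mask, count = sum(truth_union),
                 per_blob = vapply(cal_masks, sum, integer(1))),
    true_normalized = vapply(scene$calcium, function(e) e$level, numeric(1)) -
      dark_ref_level,
    rois = list(valve = valve,
                dark = inscribed_roi(scene$cavities[[1]]),
                outside = find_outside_roi(scene, sec)),
    scene = scene, acq = acq), class = "phantom_render")
}

#' @export
print.phantom_render <- function(x, ...) {
  cat(sprintf("<phantom_render> %dx%d image, %d true calcium pixel(s) in %d blob(s)\n",
              nrow(x$image), ncol(x$image), x$truth$count,
              length(x$truth$per_blob)))
  invisible(x)
}

# Exact ground-truth calcium_mask from a logical matrix, in image frame.
mask_from_logical <- function(m, roi) {
  idx <- which(t(m))
  w <- ncol(m)
  coords <- cbind(row = (idx - 1L) %/% w, col = (idx - 1L) %% w)
  storage.mode(coords) <- "integer"
  structure(list(roi = roi, coords = coords), class = "calcium_mask")
}

# Valve ROI: bounding box of the calcium blobs plus a tissue margin.
blob_bbox_roi <- function(scene, cal_masks, margin = 8L) {
  m <- Reduce(`|`, cal_masks)
  rows <- range(which(apply(m, 1, any)))
  cols <- range(which(apply(m, 2, any)))
  y0 <- max(rows[1] - 1L - margin, 0L)
  x0 <- max(cols[1] - 1L - margin, 0L)
  y1 <- min(rows[2] + margin, scene$height)
  x1 <- min(cols[2] + margin, scene$width)
  rect_roi(x0, y0, x1 - x0, y1 - y0)
}

# Largest axis-aligned rectangle inscribed in an ellipse (+ safety inset).
inscribed_roi <- function(e) {
  hr <- floor(e$semi_row / sqrt(2)) - 1
  hc <- floor(e$semi_col / sqrt(2)) - 1
  rect_roi(round(e$center[2]) - hc - 1L, round(e$center[1]) - hr - 1L,
           2L * hc + 1L, 2L * hr + 1L)
}

# A 16x16 corner patch fully outside the sector.
find_outside_roi <- function(scene, sec, size = 16L) {
  corners <- list(c(0L, 0L), c(0L, scene$width - size),
                  c(scene$height - size, 0L),
                  c(scene$height - size, scene$width - size))
  for (co in corners) {
    rows <- (co[1] + 1L):(co[1] + size)
    cols <- (co[2] + 1L):(co[2] + size)
    if (!any(sec[rows, cols])) return(rect_roi(co[2], co[1], size, size))
  }
  stop("no corner of the canvas lies outside the sector", call. = FALSE)
}

#' Render a scene under a list of acquisition settings
#'
#' The synthetic counterpart of repeated acquisitions of one patient under
#' varying machine settings. Per-render seeds follow
#' [acquisition_settings()] semantics (shared scene speckle unless a
#' setting carries its own seed).
#'
#' @param scene a [phantom_scene()].
#' @param settings_list non-empty list of [acquisition_settings()].
#' @return list with `renders` (list of [render_phantom()] results) and
#'   `manifest` (one data-frame row per render: settings and ground truth).
#' @export
render_grid <- function(scene, settings_list) {
  stopifnot(length(settings_list) >= 1)
  renders <- lapply(settings_list, function(a) render_phantom(scene, a))
  manifest <- do.call(rbind, lapply(seq_along(renders), function(i) {
    a <- settings_list[[i]]
    data.frame(image = i, postproc_gain = a$postproc_gain,
               ww = a$windowing$ww, wl = a$windowing$wl,
               compression = a$compression, noise_scale = a$noise_scale,
               seed = if (is.null(a$seed)) scene$seed else a$seed,
               truth_count = renders[[i]]$truth$count)
  }))
  list(renders = renders, manifest = manifest)
}

#' The post-processing invariance study
#'
#' `windowing_study_scene()` is the fixed scene used to test brightness
#' invariance of the normalized calcium score: intensities live in the raw
#' acquisition domain *before* display windowing (calcium 150, blood pool
#' 8, tissue 70), so that calcium stays inside every display window of the
#' study and above every adaptive threshold; speckle is moderate (Gamma
#' shape 300, ~6% SD) and belongs to the scene, since the study re-renders
#' one stored acquisition under different post-processing.
#' `windowing_study_settings()` returns the 9 acquisition variants:
#' additive gains \{0, 20, 40\} crossed with window levels \{75, 100, 125\}
#' at window width 250. `windowing_study_config()` is the matching
#' pipeline configuration; it uses the permissive base threshold 140
#' appropriate to raw-domain intensities.
#'
#' @param seed scene RNG seed.
#' @return a [phantom_scene()]; a list of 9 [acquisition_settings()]; a
#'   [pipeline_config()], respectively.
#' @export
windowing_study_scene <- function(seed = 1L) {
  phantom_scene(tissue_level = 70,
                cavities = list(list(center = c(130, 96), semi_row = 26,
                                     semi_col = 20, level = 8, noise_mult = 1)),
                calcium = list(list(center = c(70, 96), semi_row = 10,
                                    semi_col = 12, level = 150)),
                speckle_shape = 300, seed = seed)
}

#' @rdname windowing_study_scene
#' @export
windowing_study_settings <- function() {
  out <- list()
  for (g in c(0, 20, 40))
    for (wl in c(75, 100, 125))
      out[[length(out) + 1L]] <- acquisition_settings(
        postproc_gain = g, windowing = windowing_params(250, wl))
  out
}

#' @rdname windowing_study_scene
#' @param render a [render_phantom()] result from the study scene.
#' @export
windowing_study_config <- function(render) {
  pipeline_config(valve_roi = render$rois$valve, dark_roi = render$rois$dark,
                  outside_roi = render$rois$outside,
                  enhance = enhance_config(base_threshold = 140))
}
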