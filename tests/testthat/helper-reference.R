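# Naive per-pixel reference implementations, kept deliberately independent
# of the package's vectorized / compiled code paths. Used as oracles.

naive_median_blur <- function(m, k) {
  h <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- integer(0)
      for (di in -h:h) {
        for (dj in -h:h) {
          ci <- min(max(i + di, 1L), nr)  # replicate padding
          cj <- min(max(j + dj, 1L), nc)
          vals <- c(vals, m[ci, cj])
        }
      }
      out[i, j] <- sort(vals)[(k * k + 1L) %/% 2L]
    }
  }
  out
}

naive_binarize <- function(m, thr) {
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- if (m[i, j] > thr) 255L else 0L
  out
}

naive_dilate <- function(m, k, iters) {
  h <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iters)) {
    out <- matrix(0L, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        for (di in -h:h) {
          for (dj in -h:h) {
            ci <- i + di; cj <- j + dj
            if (ci >= 1 && ci <= nr && cj >= 1 && cj <= nc && m[ci, cj] > 0)
              out[i, j] <- 255L
          }
        }
      }
    }
    m <- out
  }
  m
}

# Naive detection path: blur -> adaptive threshold -> dilate, returning the
# set of white pixels inside the valve ROI as 0-based (row, col) coords.
naive_pipeline_mask <- function(m, valve, dark, base = 160,
                                blur_k = 5L, dil_k = 3L, dil_it = 1L) {
  b <- naive_median_blur(m, blur_k)
  dvals <- b[(dark$y0 + 1):(dark$y0 + dark$height),
             (dark$x0 + 1):(dark$x0 + dark$width)]
  thr <- base + mean(dvals)
  bin <- naive_binarize(b, thr)
  bin <- naive_dilate(bin, dil_k, dil_it)
  coords <- NULL
  for (r in valve$y0:(valve$y0 + valve$height - 1)) {
    for (cl in valve$x0:(valve$x0 + valve$width - 1)) {
      if (bin[r + 1, cl + 1] == 255L) coords <- rbind(coords, c(r, cl))
    }
  }
  coords
}

# Random 8-bit test image with a guaranteed-dark top-left patch so the
# adaptive threshold cannot saturate.
random_test_image <- function(nr, nc, dark_patch = 4L) {
  m <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  m[seq_len(dark_patch), seq_len(dark_patch)] <-
    sample(0:40, dark_patch * dark_patch, replace = TRUE)
  gray_image(m)
}

# Wrap a 0/255 integer matrix as a binary image via the public surface.
as_bin <- function(m) binarize(gray_image(m), 0)
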