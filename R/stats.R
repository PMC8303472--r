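#' Population standard deviation
#'
#' Dispersion with divisor `n` (not `n - 1`): `sqrt(mean((v - mean(v))^2))`.
#' This is the convention under which the published across-acquisition
#' stability figures for the normalized calcium intensities reproduce;
#' `sample = TRUE` gives the `n - 1` (unbiased) variant.
#'
#' @param values numeric vector, length >= 1.
#' @param sample logical; use divisor `n - 1` instead (default `FALSE`).
#' @return the standard deviation.
#' @examples
#' population_sd(c(1, 2, 3))  # sqrt(2/3)
#' @export
population_sd <- function(values, sample = FALSE) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(values)) stop("'values' contains missing values", call. = FALSE)
  if (sample) {
    if (length(values) < 2L) stop("sample SD needs n >= 2", call. = FALSE)
    return(stats::sd(values))
  }
  sqrt(mean((values - mean(values))^2))
}

#' Paired white-pixel count / planimetry series
#'
#' @param labels identifiers (coerced to character).
#' @param x white-pixel counts (integer >= 0).
#' @param y planimetry areas in cm^2 (> 0).
#' @return an object of class `paired_series`.
#' @export
paired_series <- function(labels, x, y) {
  if (length(x) != length(y) || (length(labels) && length(labels) != length(x)))
    stop("labels, x and y must have equal lengths", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 pairs are required", call. = FALSE)
  if (any(x < 0)) stop("white-pixel counts must be >= 0", call. = FALSE)
  if (any(y <= 0)) stop("planimetry areas must be > 0", call. = FALSE)
  structure(list(labels = as.character(labels), x = as.numeric(x),
                 y = as.numeric(y)), class = "paired_series")
}

#' Pearson agreement between pixel counts and planimetry
#'
#' Product-moment correlation `r`, the coefficient of determination
#' `r^2 = r * r`, and the two-sided p-value from the t-test with `n - 2`
#' degrees of freedom, `t = r * sqrt(n - 2) / sqrt(1 - r^2)` (via
#' [stats::cor.test()]).
#'
#' @param series a [paired_series()], or anything with numeric `x` and `y`
#'   components (e.g. a data frame with those columns).
#' @return an object of class `agreement_result` with fields `pearson_r`,
#'   `r_squared`, `p_value`, `n`.
#' @export
pearson_agreement <- function(series) {
  x <- series$x
  y <- series$y
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired x/y of equal length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("r is undefined for a zero-variance series", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(pearson_r = r, r_squared = r * r, p_value = ct$p.value,
                 n = length(x)), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> r = %.4f, r^2 = %.4f, p = %.3g, n = %d\n",
              x$pearson_r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Across-acquisition stability of the normalized score
#'
#' Population SD of the normalized mean (or median) calcium intensity over
#' repeated acquisitions of the same subject. A smaller value means the
#' normalization better cancels acquisition-setting changes; comparing the
#' mean- and median-based statistics, and dark ROIs placed in different
#' cavities, uses exactly this number.
#'
#' @param reports list of `calcium_report` objects (length >= 2), or a
#'   numeric vector of already-extracted normalized statistics.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return the population SD (grey levels).
#' @export
acquisition_stability <- function(reports, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  vals <- if (is.numeric(reports)) {
    reports
  } else {
    stopifnot(all(vapply(reports, inherits, logical(1), "calcium_report")))
    field <- paste0("normalized_", statistic)
    vapply(reports, function(r) r[[field]], numeric(1))
  }
  if (length(vals) < 2L) stop("need at least 2 acquisitions", call. = FALSE)
  if (anyNA(vals))
    stop("some reports have no calcium statistics (empty masks)", call. = FALSE)
  population_sd(vals)
}

#' Read a paired validation CSV
#'
#' Expects columns `id`, `white_pixels`, `planimetry_cm2`.
#'
#' @param path CSV path.
#' @return a [paired_series()].
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "white_pixels", "planimetry_cm2")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "), call. = FALSE)
  paired_series(df$id, df$white_pixels, df$planimetry_cm2)
}

#' Scatter plot of counts against planimetry with fitted line
#'
#' @param series a [paired_series()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_agreement <- function(series, path) {
  ag <- pearson_agreement(series)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(series$x, series$y, pch = 19, col = "steelblue",
                 xlab = "Number of white pixels",
                 ylab = expression(Planimetry ~ area ~ (cm^2)),
                 main = sprintf("r = %.2f (n = %d)", ag$pearson_r, ag$n))
  graphics::abline(stats::lm(series$y ~ series$x), col = "grey40", lty = 2)
  invisible(path)
}
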