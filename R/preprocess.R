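# Image preprocessing: imputation, smoothing, intensity normalization,
# ICV normalization and gray-level quantization.
#
# Images are plain numeric matrices (rows = image rows), 8-bit intensities in
# [0, 255] with NA marking missing pixels. File inputs (PNG) carry no missing
# pixels; NA arises only from synthetic injection.

#' Preprocessing configuration
#'
#' @param smooth_sigma Gaussian smoothing standard deviation in pixels (> 0).
#' @param levels Number of gray levels `L` used for quantization (2..256).
#'   GLCMs are `L x L`, so `L` controls how well a small image or window can
#'   populate the matrix; 32 is a practical default for 128 x 128 inputs.
#' @param icv Optional intracranial-volume denominator (> 0) for
#'   [normalize_by_icv()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_sigma = 1.0, levels = 32L, icv = NULL) {
  if (!is.numeric(smooth_sigma) || length(smooth_sigma) != 1L || smooth_sigma <= 0)
    stop("`smooth_sigma` must be a single positive number")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L || levels > 256L)
    stop("`levels` must be an integer in [2, 256]")
  if (!is.null(icv) && (!is.numeric(icv) || icv <= 0))
    stop("`icv` must be a positive number")
  structure(list(smooth_sigma = smooth_sigma, levels = levels, icv = icv),
            class = "preprocess_config")
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("image must be at least 2 x 2")
  invisible(image)
}

#' Replace missing pixels by the mean of the observed pixels
#'
#' Every `NA` pixel is filled with the arithmetic mean of all non-missing
#' pixels; observed pixels are left untouched. Idempotent.
#'
#' @param image Numeric matrix with `NA` marking missing pixels.
#' @return The image with no missing pixels.
#' @export
mean_impute <- function(image) {
  check_image(image)
  miss <- is.na(image)
  if (!any(miss)) return(image)
  if (all(miss)) stop("cannot impute: every pixel is missing")
  image[miss] <- mean(image[!miss])
  image
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable 2D Gaussian convolution. The kernel is truncated at
#' `ceiling(3 * sigma)` and renormalized to sum one, so constant images are
#' preserved exactly; boundaries are handled by reflection, which conserves
#' total pixel mass.
#'
#' @param image Numeric matrix without missing pixels.
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(image, sigma) {
  check_image(image)
  if (anyNA(image)) stop("image has missing pixels; run mean_impute() first")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  r <- as.integer(ceiling(3 * sigma))
  if (r < 1L) return(image)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smoothed <- convolve_1d_reflect(image, k, r, margin = 1L)
  convolve_1d_reflect(smoothed, k, r, margin = 2L)
}

# 1D convolution along rows (margin = 1) or columns (margin = 2) with
# reflective padding; kernel has 2r + 1 taps.
convolve_1d_reflect <- function(image, kernel, r, margin) {
  n <- dim(image)[margin]
  idx <- reflect_index(seq_len(n + 2L * r) - r, n)
  padded <- if (margin == 1L) image[idx, , drop = FALSE] else image[, idx, drop = FALSE]
  out <- matrix(0, nrow(image), ncol(image))
  for (t in seq_along(kernel)) {
    sl <- seq_len(n) + (t - 1L)
    shifted <- if (margin == 1L) padded[sl, , drop = FALSE] else padded[, sl, drop = FALSE]
    out <- out + kernel[t] * shifted
  }
  out
}

# Map out-of-range positions into [1, n] by mirror reflection (a b c -> b a|a b c|c b).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Min-max intensity normalization
#'
#' Rescales pixel values to span `[0, 1]`. A constant image maps to all
#' zeros (documented convention, so the operation is total).
#'
#' @param image Numeric matrix without missing pixels.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(image) {
  check_image(image)
  if (anyNA(image)) stop("image has missing pixels; run mean_impute() first")
  lo <- min(image)
  hi <- max(image)
  if (hi - lo <= 0) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) / (hi - lo)
}

#' Normalize a volumetric measurement by intracranial volume
#'
#' @param raw_measurement Measurement in volume units.
#' @param icv Intracranial volume in the same units (> 0).
#' @return The dimensionless ratio `raw_measurement / icv`.
#' @export
normalize_by_icv <- function(raw_measurement, icv) {
  if (!is.numeric(icv) || length(icv) != 1L || icv <= 0)
    stop("`icv` must be a single positive number")
  raw_measurement / icv
}

#' Quantize an image to L gray levels
#'
#' Uniform binning of the value range into `L` equal-width bins. Inputs in
#' `[0, 1]` (normalized) are used as-is; inputs exceeding 1 are assumed to be
#' raw 8-bit values and are rescaled by 255 first. Monotone: `v1 <= v2`
#' implies `q(v1) <= q(v2)`.
#'
#' @param image Numeric matrix with values in `[0, 1]` or `[0, 255]`.
#' @param levels Number of gray levels `L` (2..256).
#' @return Integer-valued matrix with entries in `[0, L - 1]`.
#' @export
quantize <- function(image, levels) {
  check_image(image)
  if (anyNA(image)) stop("image has missing pixels; run mean_impute() first")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L || levels > 256L)
    stop("`levels` must be an integer in [2, 256]")
  v <- image
  if (max(v) > 1) v <- v / 255
  if (min(v) < 0 || max(v) > 1 + 1e-9)
    stop("image values must lie in [0, 1] or [0, 255]")
  q <- floor(v * levels)
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  dim(q) <- dim(image)
  q
}

#' Motion-correction hook (identity)
#'
#' Placeholder stage so the pipeline mirrors a full MRI preprocessing chain;
#' rigid-body registration is out of scope and the input is returned
#' unchanged.
#' @param image Numeric matrix.
#' @return The input, unchanged.
#' @export
motion_correct <- function(image) image

#' Slice-timing compensation hook (identity)
#'
#' Placeholder stage, see [motion_correct()]. Returns the input unchanged.
#' @param image Numeric matrix.
#' @return The input, unchanged.
#' @export
slice_time_compensate <- function(image) image

#' Run the full preprocessing chain
#'
#' impute -> (identity hooks) -> smooth -> normalize -> quantize.
#'
#' @param image Numeric matrix, 8-bit intensities with optional `NA`s.
#' @param config A [preprocess_config()].
#' @return Integer matrix of gray levels in `[0, levels - 1]`.
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  x <- mean_impute(image)
  x <- motion_correct(x)
  x <- slice_time_compensate(x)
  x <- gaussian_smooth(x, config$smooth_sigma)
  x <- normalize_intensity(x)
  quantize(x, config$levels)
}

#' Read an 8-bit grayscale image
#'
#' Reads PNG via the `png` package; color inputs are collapsed to grayscale
#' by the channel average. Values are returned on the 0..255 scale.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a * 255
}

#' Write an image as 8-bit grayscale PNG
#'
#' @param image Numeric matrix; values in `[0, 255]` (or `[0, 1]`, written
#'   as-is when the maximum does not exceed 1).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  v <- if (max(image, na.rm = TRUE) > 1) image / 255 else image
  v[v < 0] <- 0
  v[v > 1] <- 1
  png::writePNG(v, target = path, dpi = NULL)
  invisible(path)
}
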