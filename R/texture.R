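# Gray-level co-occurrence matrices and Haralick texture features.
#
# A GLCM for offset (d, theta) is the L x L matrix of normalized
# co-occurrence probabilities of gray-level pairs at that pixel offset.
# Angles follow the standard image-processing convention, (row, col)
# offsets with row 1 at the top:
#   theta = 0     -> ( 0,  d)
#   theta = pi/4  -> (-d,  d)
#   theta = pi/2  -> (-d,  0)
#   theta = 3pi/4 -> (-d, -d)

HARALICK_FEATURES <- c("contrast", "energy", "correlation",
                       "homogeneity", "entropy", "dissimilarity")

#' Texture extraction configuration
#'
#' @param distances Positive integer pixel-pair distances.
#' @param angles Offset directions in radians; the supported set is
#'   `c(0, pi/4, pi/2, 3*pi/4)`.
#' @param levels Gray-level count `L` used to quantize before pair counting.
#' @param window `NULL` for whole-image GLCMs (the default), or an odd
#'   integer window size for sliding-window extraction, in which per-window
#'   feature values are averaged.
#' @param stride Step between window origins in window mode.
#' @param symmetric Count each pixel pair in both directions (default).
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(distances = c(1L, 3L, 5L, 7L),
                           angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                           levels = 32L, window = NULL, stride = 1L,
                           symmetric = TRUE) {
  distances <- as.integer(distances)
  if (any(is.na(distances)) || any(distances < 1L))
    stop("`distances` must be positive integers")
  for (a in angles) angle_offset(1L, a)  # validates the angle set
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
      stop("`window` must be an odd integer >= 3")
  }
  structure(list(distances = distances, angles = angles,
                 levels = as.integer(levels), window = window,
                 stride = as.integer(stride), symmetric = isTRUE(symmetric)),
            class = "texture_config")
}

# (row, col) offset for a distance/angle pair.
angle_offset <- function(d, theta) {
  tol <- 1e-9
  if (abs(theta) < tol) c(0L, d)
  else if (abs(theta - pi / 4) < tol) c(-d, d)
  else if (abs(theta - pi / 2) < tol) c(-d, 0L)
  else if (abs(theta - 3 * pi / 4) < tol) c(-d, -d)
  else stop("unsupported angle: ", theta,
            " (use 0, pi/4, pi/2 or 3*pi/4)")
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts all in-bounds ordered pixel pairs at offset `(d, theta)`, adds the
#' transposed counts in symmetric mode, and normalizes to sum one.
#'
#' @param qimage Integer-valued matrix with entries in `[0, levels - 1]`.
#' @param d Pixel-pair distance (positive integer).
#' @param theta Angle in radians, one of 0, pi/4, pi/2, 3pi/4.
#' @param levels Gray-level count `L`.
#' @param symmetric Count pairs in both directions.
#' @return Object of class `glcm`: list with `P` (L x L probability matrix),
#'   `d`, `theta`, `levels`, `symmetric`.
#' @export
compute_glcm <- function(qimage, d, theta, levels, symmetric = TRUE) {
  check_image(qimage)
  levels <- as.integer(levels)
  if (min(qimage) < 0L || max(qimage) > levels - 1L)
    stop("quantized image values must lie in [0, levels - 1]")
  off <- angle_offset(as.integer(d), theta)
  h <- nrow(qimage); w <- ncol(qimage)
  rows <- seq_len(h)[seq_len(h) + off[1] >= 1L & seq_len(h) + off[1] <= h]
  cols <- seq_len(w)[seq_len(w) + off[2] >= 1L & seq_len(w) + off[2] <= w]
  if (length(rows) == 0L || length(cols) == 0L)
    stop("offset (", off[1], ",", off[2], ") yields no valid pixel pair")
  i <- qimage[rows, cols, drop = FALSE]
  j <- qimage[rows + off[1], cols + off[2], drop = FALSE]
  counts <- tabulate(as.integer(i) * levels + as.integer(j) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  structure(list(P = P, d = as.integer(d), theta = theta, levels = levels,
                 symmetric = isTRUE(symmetric)),
            class = "glcm")
}

glcm_P <- function(glcm) {
  if (inherits(glcm, "glcm")) glcm$P
  else if (is.matrix(glcm)) glcm
  else stop("expected a `glcm` object or a probability matrix")
}

# i/j level grids (0-based) for an L x L GLCM.
level_grid <- function(L) {
  list(i = matrix(0:(L - 1L), L, L), j = matrix(0:(L - 1L), L, L, byrow = TRUE))
}

#' @rdname haralick
#' @export
glcm_contrast <- function(glcm) {
  P <- glcm_P(glcm)
  g <- level_grid(nrow(P))
  sum((g$i - g$j)^2 * P)
}

#' @rdname haralick
#' @export
glcm_energy <- function(glcm) {
  P <- glcm_P(glcm)
  sum(P^2)
}

#' @rdname haralick
#' @export
glcm_correlation <- function(glcm) {
  P <- glcm_P(glcm)
  L <- nrow(P)
  lv <- 0:(L - 1L)
  px <- rowSums(P)
  py <- colSums(P)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px))
  sy <- sqrt(sum((lv - my)^2 * py))
  if (sx * sy < 1e-12) return(0)
  g <- level_grid(L)
  (sum(g$i * g$j * P) - mx * my) / (sx * sy)
}

#' @rdname haralick
#' @export
glcm_homogeneity <- function(glcm) {
  P <- glcm_P(glcm)
  g <- level_grid(nrow(P))
  sum(P / (1 + abs(g$i - g$j)))
}

#' @rdname haralick
#' @export
glcm_entropy <- function(glcm, eps = 1e-12) {
  P <- glcm_P(glcm)
  if (eps <= 0) stop("`eps` must be positive")
  -sum(P * log2(P + eps))
}

#' Haralick features of a GLCM
#'
#' Scalar texture descriptors of a co-occurrence matrix `P` with gray
#' levels `i, j` in `0..L-1`:
#' \describe{
#'   \item{contrast}{`sum (i-j)^2 P(i,j)` — local intensity variation.}
#'   \item{energy}{`sum P(i,j)^2` (angular second moment) — uniformity;
#'     equals 1 iff a single cell carries all mass.}
#'   \item{correlation}{`(sum i j P(i,j) - mu_x mu_y) / (sigma_x sigma_y)`
#'     over the marginal moments; 0 by convention when a marginal is
#'     degenerate (`sigma_x sigma_y < 1e-12`).}
#'   \item{homogeneity}{`sum P(i,j) / (1 + |i-j|)` (inverse difference
#'     moment) — closeness of mass to the diagonal.}
#'   \item{entropy}{`-sum P(i,j) log2(P(i,j) + eps)` — texture randomness
#'     in bits; `eps` regularizes empty cells.}
#'   \item{dissimilarity}{`sum |i-j| P(i,j)`.}
#' }
#'
#' @param glcm A `glcm` object from [compute_glcm()] or a bare probability
#'   matrix.
#' @param eps Regularizer added inside the entropy logarithm.
#' @return A single numeric value.
#' @name haralick
NULL

#' @rdname haralick
#' @export
glcm_dissimilarity <- function(glcm) {
  P <- glcm_P(glcm)
  g <- level_grid(nrow(P))
  sum(abs(g$i - g$j) * P)
}

haralick_of_glcm <- function(glcm) {
  c(contrast      = glcm_contrast(glcm),
    energy        = glcm_energy(glcm),
    correlation   = glcm_correlation(glcm),
    homogeneity   = glcm_homogeneity(glcm),
    entropy       = glcm_entropy(glcm),
    dissimilarity = glcm_dissimilarity(glcm))
}

#' Names of the Haralick feature vector for a texture configuration
#'
#' Deterministic ordering: distances vary slowest, then angles (index 0..),
#' then the six features. Names have the form `d{d}_a{angle-index}_{feature}`.
#'
#' @param config A [texture_config()].
#' @return Character vector of length
#'   `length(distances) * length(angles) * 6`.
#' @export
haralick_feature_names <- function(config = texture_config()) {
  unlist(lapply(config$distances, function(d)
    lapply(seq_along(config$angles) - 1L, function(ai)
      paste0("d", d, "_a", ai, "_", HARALICK_FEATURES))))
}

#' Extract the Haralick feature vector of an image
#'
#' For every `(distance, angle)` pair of the configuration, builds the GLCM
#' of the quantized image and computes the six Haralick features. In
#' whole-image mode (default) a single GLCM per offset is used; in window
#' mode the per-window feature values are averaged over a sliding window.
#'
#' @param qimage Integer-valued quantized image in `[0, levels - 1]`, e.g.
#'   from [preprocess_image()] or [quantize()].
#' @param config A [texture_config()].
#' @return Named numeric vector ordered as [haralick_feature_names()].
#' @export
extract_features <- function(qimage, config = texture_config()) {
  check_image(qimage)
  dmax <- max(config$distances)
  if (nrow(qimage) <= dmax || ncol(qimage) <= dmax)
    stop("image smaller than the largest pixel-pair distance")
  if (!is.null(config$window) &&
      (nrow(qimage) < config$window || ncol(qimage) < config$window))
    stop("image smaller than the extraction window")
  vals <- numeric(0)
  for (d in config$distances) {
    for (theta in config$angles) {
      if (is.null(config$window)) {
        f <- haralick_of_glcm(compute_glcm(qimage, d, theta, config$levels,
                                           config$symmetric))
      } else {
        f <- window_mean_features(qimage, d, theta, config)
      }
      vals <- c(vals, f)
    }
  }
  names(vals) <- haralick_feature_names(config)
  vals
}

# Average of per-window Haralick features over a sliding window.
window_mean_features <- function(qimage, d, theta, config) {
  w <- config$window
  s <- config$stride
  r0 <- seq(1L, nrow(qimage) - w + 1L, by = s)
  c0 <- seq(1L, ncol(qimage) - w + 1L, by = s)
  acc <- numeric(length(HARALICK_FEATURES))
  n <- 0L
  for (r in r0) for (cc in c0) {
    win <- qimage[r:(r + w - 1L), cc:(cc + w - 1L)]
    if (w <= d) next  # offset does not fit in this window
    acc <- acc + haralick_of_glcm(compute_glcm(win, d, theta, config$levels,
                                               config$symmetric))
    n <- n + 1L
  }
  if (n == 0L) stop("window ", w, " cannot accommodate distance ", d)
  acc / n
}
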