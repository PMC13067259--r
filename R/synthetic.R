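# Synthetic class-labelled textured images and planted-signal feature
# tables. Classes are Gaussian random fields differing in correlation
# length (smoothness) and amplitude, which orders their expected GLCM
# statistics by construction: rougher classes have strictly higher
# contrast at short offsets.

#' Synthetic image-set configuration
#'
#' Emulates a balanced 4-class 8-bit 128 x 128 grayscale dataset. Class
#' smoothness values must be strictly increasing so the expected GLCM
#' contrast is strictly ordered across classes (class 0 roughest).
#'
#' @param n_classes Number of classes.
#' @param n_per_class Images per class.
#' @param size Image side length in pixels.
#' @param class_smoothness Per-class Gaussian-field correlation lengths
#'   (kernel sigma in pixels), strictly increasing.
#' @param class_contrast Per-class amplitude scalings.
#' @param missing_fraction Fraction of pixels replaced by `NA` in each
#'   image, in `[0, 0.2]`.
#' @param mask Apply an elliptical brain-like mask with zero background.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 4L, n_per_class = 100L, size = 128L,
                             class_smoothness = c(0.5, 1.0, 2.0, 4.0),
                             class_contrast = c(1.0, 0.9, 0.8, 0.7),
                             missing_fraction = 0, mask = FALSE, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (length(class_smoothness) != n_classes ||
      length(class_contrast) != n_classes)
    stop("per-class parameter lengths must equal `n_classes`")
  if (any(diff(class_smoothness) <= 0))
    stop("`class_smoothness` must be strictly increasing")
  if (missing_fraction < 0 || missing_fraction > 0.2)
    stop("`missing_fraction` must lie in [0, 0.2]")
  structure(list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
                 size = as.integer(size),
                 class_smoothness = class_smoothness,
                 class_contrast = class_contrast,
                 missing_fraction = missing_fraction, mask = isTRUE(mask),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one textured image of a class
#'
#' White noise is smoothed by a Gaussian kernel of the class's correlation
#' length, standardized, scaled by the class amplitude, shifted to
#' mid-gray, clipped to `[0, 255]` and rounded to 8 bits. Deterministic
#' given `seed`.
#'
#' @param class_index 0-based class index.
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this image.
#' @return Numeric matrix of 8-bit intensities (with `NA`s when
#'   `missing_fraction > 0`).
#' @export
generate_image <- function(class_index, config = synthetic_config(),
                           seed = 1L) {
  class_index <- as.integer(class_index)
  if (class_index < 0L || class_index >= config$n_classes)
    stop("`class_index` must lie in [0, n_classes - 1]")
  s <- config$size
  with_seed(seed, {
    field <- matrix(stats::rnorm(s * s), s, s)
    field <- gaussian_smooth(field, config$class_smoothness[class_index + 1L])
    field <- (field - mean(field)) / stats::sd(field)
    amp <- 60 * config$class_contrast[class_index + 1L]
    img <- 127.5 + amp * field
    img[img < 0] <- 0
    img[img > 255] <- 255
    img <- round(img)
    if (config$mask) {
      cx <- (s + 1) / 2
      rr <- outer(seq_len(s), seq_len(s), function(r, c)
        ((r - cx) / (0.45 * s))^2 + ((c - cx) / (0.38 * s))^2)
      img[rr > 1] <- 0
    }
    if (config$missing_fraction > 0) {
      n_miss <- round(config$missing_fraction * s * s)
      img[sample(s * s, n_miss)] <- NA_real_
    }
    img
  })
}

#' Generate a balanced labelled image set
#'
#' `n_classes * n_per_class` images in a seeded shuffled order. When `dir`
#' is given, images are written as PNG into one folder per class
#' (`class_0`, `class_1`, ...) with a `manifest.csv` (path, label) beside
#' them; images with injected missing pixels are imputed before writing
#' since PNG cannot carry missingness.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return List with `images` (list of matrices, `NULL`ed when written to
#'   disk), `labels` (0-based integer vector), and `manifest` (data.frame
#'   with `image_id`, `label`, and `path` when written).
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  n_total <- config$n_classes * config$n_per_class
  labels <- rep(seq_len(config$n_classes) - 1L, each = config$n_per_class)
  ord <- with_seed(config$seed, sample(n_total))
  labels <- labels[ord]
  image_seeds <- config$seed + 7919L * seq_len(n_total)
  images <- lapply(seq_len(n_total), function(k)
    generate_image(labels[k], config, seed = image_seeds[k]))
  ids <- sprintf("img_%04d", seq_len(n_total))
  manifest <- data.frame(image_id = ids, label = labels,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n_total)
    for (k in seq_len(n_total)) {
      cls_dir <- file.path(dir, paste0("class_", labels[k]))
      dir.create(cls_dir, showWarnings = FALSE)
      paths[k] <- file.path(cls_dir, paste0(ids[k], ".png"))
      write_image(mean_impute(images[[k]]), paths[k])
    }
    manifest$path <- paths
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    images <- NULL
  }
  list(images = images, labels = labels, manifest = manifest)
}

#' Planted-signal feature-table configuration
#'
#' @param n_samples Total sample count.
#' @param k_informative Number of class-informative columns (>= 1).
#' @param m_noise Number of pure-noise columns.
#' @param effect Between-class mean separation in within-class standard
#'   deviations (> 0).
#' @param n_classes Number of balanced classes.
#' @param seed Integer seed.
#' @return A list of class `planted_config`.
#' @export
planted_config <- function(n_samples = 400L, k_informative = 4L,
                           m_noise = 12L, effect = 2.0, n_classes = 4L,
                           seed = 1L) {
  if (effect < 0) stop("`effect` must be non-negative")
  if (k_informative < 1L) stop("`k_informative` must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 k_informative = as.integer(k_informative),
                 m_noise = as.integer(m_noise), effect = effect,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "planted_config")
}

#' Generate a planted-signal feature table
#'
#' Informative columns are unit-variance Gaussians whose class means are
#' separated by `effect` within-class standard deviations; noise columns
#' are i.i.d. standard normal, independent of class. Columns are shuffled
#' (seeded); the ground-truth informative positions are recorded in the
#' `informative` attribute of the result.
#'
#' @param config A [planted_config()].
#' @return A [feature_matrix()] with attribute `informative`, a logical
#'   mask over columns marking the planted signal.
#' @export
generate_feature_table <- function(config = planted_config()) {
  n <- config$n_samples
  k <- config$k_informative
  m <- config$m_noise
  labels <- rep(seq_len(config$n_classes) - 1L, length.out = n)
  with_seed(config$seed, {
    labels <- sample(labels)
    X <- matrix(stats::rnorm(n * (k + m)), n, k + m)
    for (col in seq_len(k))
      X[, col] <- X[, col] + config$effect * labels
    perm <- sample(k + m)
    X <- X[, perm, drop = FALSE]
    mask <- (perm <= k)
    fm <- feature_matrix(X, labels, paste0("f", seq_len(k + m)))
    attr(fm, "informative") <- mask
    fm
  })
}
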