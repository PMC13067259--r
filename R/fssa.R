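# Feature-specific simulated annealing (FSSA): a continuous weight in
# [0, 1] per feature, optimized to maximize
#   a * accuracy(weighted features) - b * redundancy(weighted features).
# Unlike selection wrappers, no feature is eliminated outright; weights can
# reach exactly 0 or 1 through clipping of the Gaussian perturbation.

#' Build a feature matrix
#'
#' Container pairing a samples-by-features value matrix with per-sample
#' class labels.
#'
#' @param values Numeric matrix, samples in rows.
#' @param labels Vector of class labels, one per row.
#' @param feature_names Optional column identifiers.
#' @return A list of class `feature_matrix` with elements `values`,
#'   `labels`, `feature_names`.
#' @export
feature_matrix <- function(values, labels, feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain missing entries")
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 feature")
  if (length(labels) != nrow(values))
    stop("labels length must match the number of samples")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = feature_names),
            class = "feature_matrix")
}

#' FSSA configuration
#'
#' @param a Accuracy coefficient of the objective (>= 0).
#' @param b Redundancy coefficient of the objective (>= 0).
#' @param sigma_perturb Standard deviation of the Gaussian weight
#'   perturbation; ~5% of the unit weight range by default.
#' @param schedule An [anneal_schedule()].
#' @param val_fraction Hold-out fraction for the internal accuracy
#'   estimate, in `(0, 0.5]`.
#' @param seed Integer seed for initialization, the annealing chain and the
#'   internal validation split.
#' @param accuracy_fn Pluggable evaluator
#'   `function(fm, val_fraction, seed) -> accuracy in [0, 1]`; defaults to
#'   the fast nearest-class-centroid classifier [reference_accuracy()]. Any
#'   evaluator with the same signature (e.g. a full network training) can
#'   be substituted.
#' @return A list of class `fssa_config`.
#' @export
fssa_config <- function(a = 1.0, b = 0.5, sigma_perturb = 0.05,
                        schedule = anneal_schedule(), val_fraction = 0.25,
                        seed = 1L, accuracy_fn = reference_accuracy) {
  if (a < 0 || b < 0) stop("`a` and `b` must be non-negative")
  if (sigma_perturb <= 0) stop("`sigma_perturb` must be positive")
  if (val_fraction <= 0 || val_fraction > 0.5)
    stop("`val_fraction` must lie in (0, 0.5]")
  structure(list(a = a, b = b, sigma_perturb = sigma_perturb,
                 schedule = schedule, val_fraction = val_fraction,
                 seed = as.integer(seed), accuracy_fn = accuracy_fn),
            class = "fssa_config")
}

#' Apply per-feature weights
#'
#' Column `x` of the result is `w[x]` times column `x` of the input; labels
#' are untouched.
#'
#' @param F A [feature_matrix()].
#' @param w Numeric weight vector, one entry per feature.
#' @return A weighted `feature_matrix`.
#' @export
apply_weights <- function(F, w) {
  stopifnot(inherits(F, "feature_matrix"))
  if (length(w) != ncol(F$values))
    stop("weight length (", length(w), ") does not match feature count (",
         ncol(F$values), ")")
  out <- F
  out$values <- sweep(F$values, 2L, w, `*`)
  out
}

#' Mean absolute pairwise feature correlation
#'
#' Redundancy of a (weighted) feature matrix: the mean over all unordered
#' feature pairs of the absolute Pearson correlation between the two
#' columns. Pairs involving a constant column contribute 0; a
#' single-feature matrix returns 0.
#'
#' @param Fw A [feature_matrix()] (typically weighted).
#' @return Scalar in `[0, 1]`.
#' @export
redundancy <- function(Fw) {
  stopifnot(inherits(Fw, "feature_matrix"))
  p <- ncol(Fw$values)
  if (p < 2L) return(0)
  cc <- suppressWarnings(stats::cor(Fw$values))
  cc[!is.finite(cc)] <- 0
  up <- abs(cc[upper.tri(cc)])
  mean(up)
}

#' Nearest-class-centroid hold-out accuracy
#'
#' The default accuracy evaluator inside the FSSA objective: a seeded
#' stratified split into train and validation parts, class centroids fitted
#' on the train part over (weighted) features, and the fraction of
#' validation samples whose nearest centroid (Euclidean distance) matches
#' their label. Ties resolve to the first class in sorted label order.
#'
#' @param Fw A [feature_matrix()].
#' @param val_fraction Validation fraction in `(0, 0.5]`.
#' @param seed Integer seed controlling the split.
#' @return Accuracy in `[0, 1]`.
#' @export
reference_accuracy <- function(Fw, val_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(Fw, "feature_matrix"))
  labels <- Fw$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs at least 2 samples")
  val_idx <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      n_val <- max(1L, floor(length(idx) * val_fraction))
      sample(idx, n_val)
    }))
  })
  train_idx <- setdiff(seq_along(labels), val_idx)
  X_tr <- Fw$values[train_idx, , drop = FALSE]
  y_tr <- labels[train_idx]
  centroids <- t(vapply(classes, function(cl)
    colMeans(X_tr[y_tr == cl, , drop = FALSE]), numeric(ncol(X_tr))))
  X_val <- Fw$values[val_idx, , drop = FALSE]
  # squared Euclidean distance to each centroid
  d2 <- outer(rowSums(X_val^2), rowSums(centroids^2), `+`) -
    2 * X_val %*% t(centroids)
  pred <- classes[apply(d2, 1L, which.min)]
  mean(pred == labels[val_idx])
}

#' FSSA objective
#'
#' `a * accuracy(apply_weights(F, w)) - b * redundancy(apply_weights(F, w))`,
#' with the accuracy evaluator taken from the configuration.
#'
#' @param w Weight vector in `[0, 1]^n`.
#' @param F A [feature_matrix()].
#' @param config An [fssa_config()].
#' @return Scalar objective value (maximized by [run_fssa()]).
#' @export
fssa_objective <- function(w, F, config = fssa_config()) {
  Fw <- apply_weights(F, w)
  acc <- if (config$a > 0)
    config$accuracy_fn(Fw, config$val_fraction, config$seed) else 0
  red <- if (config$b > 0) redundancy(Fw) else 0
  config$a * acc - config$b * red
}

#' Gaussian weight perturbation with clipping
#'
#' Adds independent `N(0, sigma^2)` noise to every coordinate, then clips to
#' `[0, 1]`. Clipping gives positive probability to the exact boundary
#' values 0 and 1, which lets the redundancy penalty silence a feature
#' completely.
#'
#' @param w Weight vector.
#' @param sigma Noise standard deviation (> 0).
#' @return Perturbed weights in `[0, 1]^n`.
#' @export
perturb_weights <- function(w, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive")
  pmin(1, pmax(0, w + stats::rnorm(length(w), 0, sigma)))
}

#' Optimize feature weights by simulated annealing
#'
#' Initializes weights uniformly at random in `[0, 1]^n` (seeded), then runs
#' the annealing engine minimizing the negated [fssa_objective()] with
#' [perturb_weights()] proposals.
#'
#' @param F A [feature_matrix()] with class labels.
#' @param config An [fssa_config()].
#' @return List with `weights` (named, best found), `objective` (its
#'   objective value), and `trace` (the annealing trace; energies are
#'   negated objectives).
#' @export
run_fssa <- function(F, config = fssa_config()) {
  stopifnot(inherits(F, "feature_matrix"))
  n <- ncol(F$values)
  w0 <- with_seed(config$seed, stats::runif(n))
  res <- anneal(
    energy_fn = function(w) -fssa_objective(w, F, config),
    perturb_fn = function(w) perturb_weights(w, config$sigma_perturb),
    x0 = w0,
    schedule = config$schedule,
    seed = config$seed + 1L
  )
  weights <- res$best
  names(weights) <- F$feature_names
  list(weights = weights, objective = -res$best_energy, trace = res$trace)
}

#' Write / read feature weights as CSV
#'
#' Two-column CSV `feature_name, weight`.
#'
#' @param weights Named numeric weight vector.
#' @param path File path.
#' @return `write_weights` returns the path invisibly; `read_weights` the
#'   named weight vector.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(data.frame(feature_name = names(weights),
                              weight = unname(weights)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$weight, df$feature_name)
}
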