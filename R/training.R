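# Parameter optimization for the classifier: simulated annealing (the
# primary optimizer) and an optional finite-difference gradient-descent
# mode honoring a classical learning-rate/epoch/batch configuration.

#' Training configuration
#'
#' @param schedule An [anneal_schedule()] for SA mode (default: T0 = 1,
#'   gamma = 0.95, 500 iterations).
#' @param sigma_param Gaussian perturbation standard deviation on the
#'   flattened `(W, V)` parameter vector in SA mode (radians for `W`).
#' @param lr Learning rate for gradient mode.
#' @param epochs Passes through the data in gradient mode.
#' @param batch_size Mini-batch size in gradient mode.
#' @param mode `"sa"` (default), `"gd"`, or `"sa+gd"` (SA then gradient
#'   refinement).
#' @param init_range Half-width of the uniform parameter initialization;
#'   small values start the entangling layer near the identity.
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(schedule = anneal_schedule(), sigma_param = 0.1,
                         lr = 0.01, epochs = 200L, batch_size = 32L,
                         mode = c("sa", "gd", "sa+gd"), init_range = 0.1,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (sigma_param <= 0) stop("`sigma_param` must be positive")
  if (lr <= 0 && mode != "sa") stop("`lr` must be positive")
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  structure(list(schedule = schedule, sigma_param = sigma_param, lr = lr,
                 epochs = epochs, batch_size = batch_size, mode = mode,
                 init_range = init_range, seed = as.integer(seed)),
            class = "train_config")
}

flatten_params <- function(params) c(as.vector(params$W), params$V)

unflatten_params <- function(theta, arch) {
  nW <- arch$M * arch$N
  qdnn_params(matrix(theta[seq_len(nW)], arch$M, arch$N),
              theta[nW + seq_len(arch$M)])
}

init_params <- function(arch, range, seed) {
  n <- arch$M * arch$N + arch$M
  with_seed(seed, unflatten_params(stats::runif(n, -range, range), arch))
}

#' Training energy: mean loss on a dataset
#'
#' Mean binary cross-entropy of the forward predictions under the given
#' parameters — the quantity simulated annealing minimizes.
#'
#' @param params A [qdnn_params()].
#' @param arch A [qdnn_architecture()].
#' @param X Scaled sample matrix (`N` columns, values in `[0, 1]`).
#' @param y 0/1 label vector.
#' @return Scalar mean loss.
#' @export
qdnn_energy <- function(params, arch, X, y) {
  if (NROW(X) == 0L) stop("empty data")
  mean_loss(y, qdnn_forward_batch(X, arch, params))
}

#' Train a binary head by simulated annealing
#'
#' Flattens `(W, V)` into one parameter vector, initializes it uniformly in
#' `[-init_range, init_range]` (seeded), and runs the annealing engine with
#' Gaussian perturbations minimizing [qdnn_energy()].
#'
#' @param arch A [qdnn_architecture()].
#' @param X Scaled sample matrix.
#' @param y 0/1 labels.
#' @param config A [train_config()].
#' @return List with `params` (best found), `energy` (their mean loss) and
#'   `trace` (annealing trace).
#' @export
train_sa <- function(arch, X, y, config = train_config()) {
  if (NROW(X) == 0L) stop("empty data")
  X <- as.matrix(X)
  p0 <- init_params(arch, config$init_range, config$seed)
  res <- anneal(
    energy_fn = function(theta)
      qdnn_energy(unflatten_params(theta, arch), arch, X, y),
    perturb_fn = function(theta)
      theta + stats::rnorm(length(theta), 0, config$sigma_param),
    x0 = flatten_params(p0),
    schedule = config$schedule,
    seed = config$seed + 1L
  )
  list(params = unflatten_params(res$best, arch),
       energy = res$best_energy, trace = res$trace)
}

#' Train a binary head by finite-difference gradient descent
#'
#' Central differences (step 1e-4) estimate the gradient of the mini-batch
#' mean loss; parameters are updated with a fixed learning rate over
#' seeded shuffled epochs.
#'
#' @inheritParams train_sa
#' @param params Optional starting [qdnn_params()]; defaults to the seeded
#'   uniform initialization.
#' @return List with `params` and `energy` (final full-data mean loss).
#' @export
train_gd <- function(arch, X, y, config = train_config(mode = "gd"),
                     params = NULL) {
  if (NROW(X) == 0L) stop("empty data")
  X <- as.matrix(X)
  theta <- flatten_params(
    if (is.null(params)) init_params(arch, config$init_range, config$seed)
    else params)
  h <- 1e-4
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nrow(X))
      starts <- seq(1L, nrow(X), by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nrow(X))]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        grad <- vapply(seq_along(theta), function(k) {
          tp <- theta; tp[k] <- tp[k] + h
          tm <- theta; tm[k] <- tm[k] - h
          (qdnn_energy(unflatten_params(tp, arch), arch, Xb, yb) -
             qdnn_energy(unflatten_params(tm, arch), arch, Xb, yb)) / (2 * h)
        }, numeric(1))
        theta <- theta - config$lr * grad
      }
    }
  })
  params <- unflatten_params(theta, arch)
  list(params = params, energy = qdnn_energy(params, arch, X, y))
}

#' Fit the full multiclass model
#'
#' Optionally runs FSSA on the training features, selects the `N` features
#' with the largest weights for amplitude encoding, min-max-scales them to
#' `[0, 1]` on the training data, and trains one one-vs-rest binary head
#' per class with the configured optimizer. Per-head seeds are derived from
#' the configuration seed.
#'
#' @param F A [feature_matrix()] (training data only).
#' @param arch A [qdnn_architecture()]; `arch$N` features are encoded.
#' @param config A [train_config()].
#' @param use_fssa Run FSSA feature weighting first (default `TRUE`).
#' @param fssa_cfg An [fssa_config()] used when `use_fssa` is `TRUE`.
#' @return A `qdnn_model`: architecture, per-class heads, selected feature
#'   names, scaling bounds, class labels, and FSSA weights (or `NULL`).
#' @export
fit_qdnn <- function(F, arch, config = train_config(), use_fssa = TRUE,
                     fssa_cfg = fssa_config(seed = config$seed)) {
  stopifnot(inherits(F, "feature_matrix"))
  weights <- NULL
  if (use_fssa) {
    weights <- run_fssa(F, fssa_cfg)$weights
    ranked <- order(weights, decreasing = TRUE)
  } else {
    ranked <- seq_len(ncol(F$values))
  }
  if (ncol(F$values) < arch$N)
    stop("fewer features than input qubits")
  sel <- sort(ranked[seq_len(arch$N)])
  sel_names <- F$feature_names[sel]
  Xs <- F$values[, sel, drop = FALSE]
  lo <- apply(Xs, 2L, min)
  hi <- apply(Xs, 2L, max)
  span <- ifelse(hi - lo > 0, hi - lo, 1)
  X01 <- sweep(sweep(Xs, 2L, lo), 2L, span, `/`)
  classes <- sort(unique(F$labels))
  heads <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    yb <- as.integer(F$labels == classes[ci])
    head_cfg <- config
    head_cfg$seed <- config$seed + 1000L * ci
    fit <- switch(config$mode,
      "sa" = train_sa(arch, X01, yb, head_cfg),
      "gd" = train_gd(arch, X01, yb, head_cfg),
      "sa+gd" = {
        sa <- train_sa(arch, X01, yb, head_cfg)
        train_gd(arch, X01, yb, head_cfg, params = sa$params)
      })
    heads[[ci]] <- fit$params
  }
  structure(list(arch = arch, heads = heads, classes = classes,
                 selected = sel_names, scale_lo = lo, scale_hi = hi,
                 fssa_weights = weights),
            class = "qdnn_model")
}

#' Predict class labels with a fitted model
#'
#' Applies the stored feature selection and scaling (clipping to the
#' training range), runs every head, and assigns each sample the class of
#' the largest predicted probability.
#'
#' @param object A `qdnn_model` from [fit_qdnn()].
#' @param F A [feature_matrix()] or bare feature matrix with the same
#'   feature columns.
#' @param ... Unused.
#' @return List with `labels` (predicted classes) and `scores`
#'   (samples x classes probability matrix).
#' @export
predict.qdnn_model <- function(object, F, ...) {
  values <- if (inherits(F, "feature_matrix")) F$values else as.matrix(F)
  if (!all(object$selected %in% colnames(values)))
    stop("feature columns of the model are absent from the input")
  Xs <- values[, object$selected, drop = FALSE]
  span <- ifelse(object$scale_hi - object$scale_lo > 0,
                 object$scale_hi - object$scale_lo, 1)
  X01 <- sweep(sweep(Xs, 2L, object$scale_lo), 2L, span, `/`)
  X01 <- pmin(1, pmax(0, X01))
  dim(X01) <- dim(Xs)
  scores <- vapply(object$heads, function(h)
    qdnn_forward_batch(X01, object$arch, h), numeric(nrow(X01)))
  scores <- matrix(scores, nrow = nrow(X01))
  colnames(scores) <- as.character(object$classes)
  list(labels = object$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model A `qdnn_model`.
#' @param path File path.
#' @return `write_model` returns the path invisibly; `read_model` the
#'   restored `qdnn_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    arch = list(N = model$arch$N, M = model$arch$M, K = model$arch$K),
    classes = model$classes,
    selected = model$selected,
    scale_lo = unname(model$scale_lo),
    scale_hi = unname(model$scale_hi),
    heads = lapply(model$heads, function(h)
      list(W = as.vector(h$W), V = h$V)),
    fssa_weights = if (is.null(model$fssa_weights)) NULL else
      list(names = names(model$fssa_weights),
           values = unname(model$fssa_weights))
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  arch <- qdnn_architecture(obj$arch$N, obj$arch$M, obj$arch$K)
  heads <- lapply(seq_len(nrow(obj$heads)), function(i)
    qdnn_params(matrix(unlist(obj$heads$W[i]), arch$M, arch$N),
                unlist(obj$heads$V[i])))
  w <- NULL
  if (!is.null(obj$fssa_weights))
    w <- stats::setNames(obj$fssa_weights$values, obj$fssa_weights$names)
  structure(list(arch = arch, heads = heads, classes = obj$classes,
                 selected = obj$selected,
                 scale_lo = stats::setNames(obj$scale_lo, obj$selected),
                 scale_hi = stats::setNames(obj$scale_hi, obj$selected),
                 fssa_weights = w),
            class = "qdnn_model")
}
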