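# End-to-end orchestration: simulate -> extract -> train -> evaluate,
# with file artifacts (PNG trees, feature CSVs, model JSON, metrics JSON)
# and a single global seed fanned out to per-stage seeds.

# Deterministic per-stage seed derived from the global seed and a stage
# name (small polynomial hash, kept within the 31-bit integer range).
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 101 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with one global seed. Stage seeds
#' are derived deterministically from the global seed and the stage name,
#' so stages are independently reproducible.
#'
#' @param seed Global integer seed.
#' @param simulate A [synthetic_config()] (its own seed is overridden by
#'   the derived stage seed).
#' @param preprocess A [preprocess_config()].
#' @param texture A [texture_config()].
#' @param fssa An [fssa_config()].
#' @param train A [train_config()].
#' @param arch A [qdnn_architecture()].
#' @param k Cross-validation folds.
#' @param use_fssa Run FSSA feature weighting before training.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = synthetic_config(),
                            preprocess = preprocess_config(),
                            texture = texture_config(),
                            fssa = fssa_config(),
                            train = train_config(),
                            arch = qdnn_architecture(4L, 2L),
                            k = 5L, use_fssa = TRUE) {
  simulate$seed <- stage_seed(seed, "simulate")
  fssa$seed <- stage_seed(seed, "fssa")
  train$seed <- stage_seed(seed, "train")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 preprocess = preprocess, texture = texture, fssa = fssa,
                 train = train, arch = arch, k = as.integer(k),
                 use_fssa = isTRUE(use_fssa)),
            class = "pipeline_config")
}

#' Simulate an image dataset on disk
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory for the class folders and manifest.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(config, dir) {
  ds <- generate_dataset(config$simulate, dir = dir)
  invisible(ds$manifest)
}

#' Extract Haralick features for a manifest of images
#'
#' Reads each manifest row, preprocesses the image and extracts its
#' Haralick feature vector. Unreadable images are skipped with a warning;
#' the returned table has one row per successfully processed image.
#'
#' @param manifest Data.frame with `image_id`, `label` and either `path`
#'   (files on disk) or an `images` list supplied separately.
#' @param config A [pipeline_config()].
#' @param images Optional list of in-memory image matrices matching the
#'   manifest rows (bypasses file reading).
#' @param out_csv Optional path; when given the table is also written as
#'   CSV (columns `image_id`, `label`, then the feature columns).
#' @return A [feature_matrix()] with the manifest labels; feature columns
#'   named as [haralick_feature_names()].
#' @export
run_extract <- function(manifest, config = pipeline_config(), images = NULL,
                        out_csv = NULL) {
  n <- nrow(manifest)
  fnames <- haralick_feature_names(config$texture)
  # quantization depth must match the GLCM gray-level count
  pp <- config$preprocess
  pp$levels <- config$texture$levels
  rows <- vector("list", n)
  keep <- logical(n)
  for (k in seq_len(n)) {
    img <- tryCatch({
      if (!is.null(images)) images[[k]] else read_image(manifest$path[k])
    }, error = function(e) {
      warning("skipping ", manifest$image_id[k], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    q <- preprocess_image(img, pp)
    rows[[k]] <- extract_features(q, config$texture)
    keep[k] <- TRUE
  }
  if (!any(keep)) stop("no image could be processed")
  values <- do.call(rbind, rows[keep])
  fm <- feature_matrix(values, manifest$label[keep], fnames)
  if (!is.null(out_csv)) {
    df <- data.frame(image_id = manifest$image_id[keep],
                     label = manifest$label[keep],
                     values, check.names = FALSE)
    utils::write.csv(df, out_csv, row.names = FALSE)
  }
  fm
}

#' Read a feature CSV back into a feature matrix
#'
#' @param path CSV written by [run_extract()] (columns `image_id`,
#'   `label`, features).
#' @return A [feature_matrix()].
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_matrix(as.matrix(df[, setdiff(names(df), c("image_id", "label")),
                              drop = FALSE]),
                 df$label)
}

#' Train the classifier on a feature table
#'
#' Runs FSSA (unless disabled), selects the top-`N` features, trains the
#' one-vs-rest heads, and optionally writes the model JSON and weight CSV.
#'
#' @param F A [feature_matrix()].
#' @param config A [pipeline_config()].
#' @param model_json,weights_csv Optional artifact paths.
#' @return The fitted `qdnn_model`.
#' @export
run_train <- function(F, config = pipeline_config(), model_json = NULL,
                      weights_csv = NULL) {
  model <- fit_qdnn(F, config$arch, config$train,
                    use_fssa = config$use_fssa, fssa_cfg = config$fssa)
  if (!is.null(model_json)) write_model(model, model_json)
  if (!is.null(weights_csv) && !is.null(model$fssa_weights))
    write_weights(model$fssa_weights, weights_csv)
  model
}

#' Cross-validated evaluation of the pipeline on a feature table
#'
#' Stratified k-fold cross-validation with FSSA and training refit inside
#' every training fold. With `compare_fssa = TRUE`, the same folds are
#' evaluated twice — with and without FSSA feature weighting — to quantify
#' the contribution of the weighting stage.
#'
#' @param F A [feature_matrix()].
#' @param config A [pipeline_config()].
#' @param compare_fssa Also evaluate the pipeline without FSSA.
#' @param out_json Optional path for the metrics report (JSON).
#' @return List with `with_fssa` (a [run_cv()] result) and, when
#'   requested, `without_fssa`.
#' @export
run_evaluate <- function(F, config = pipeline_config(),
                         compare_fssa = FALSE, out_json = NULL) {
  eval_seed <- stage_seed(config$seed, "evaluate")
  make_fit <- function(use_fssa) function(train_fm, fold_seed) {
    tc <- config$train; tc$seed <- fold_seed
    fc <- config$fssa; fc$seed <- fold_seed
    fit_qdnn(train_fm, config$arch, tc, use_fssa = use_fssa, fssa_cfg = fc)
  }
  out <- list(with_fssa = run_cv(F, k = config$k, seed = eval_seed,
                                 fit_fn = make_fit(config$use_fssa)))
  if (compare_fssa)
    out$without_fssa <- run_cv(F, k = config$k, seed = eval_seed,
                               fit_fn = make_fit(FALSE))
  if (!is.null(out_json)) {
    simplify <- function(cv) list(
      mean = cv$mean,
      folds = lapply(cv$folds, function(f)
        list(fold = f$fold, metrics = f$metrics,
             confusion = unname(as.matrix(f$confusion)))),
      confusion = unname(as.matrix(cv$confusion)))
    writeLines(jsonlite::toJSON(lapply(out, simplify), auto_unbox = TRUE,
                                digits = I(10)), out_json)
  }
  out
}

#' Run the complete pipeline
#'
#' simulate -> extract -> train (on all data, for the exported model) ->
#' cross-validated evaluation, writing all artifacts into `out_dir`:
#' the image tree, `features.csv`, `model.json`, `weights.csv`,
#' `metrics.json` and a `provenance.json` snapshot (seed, sizes, package
#' version). Fully reproducible for a fixed global seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param compare_fssa Also evaluate without FSSA.
#' @param keep_images Keep the PNG tree (default) or generate in memory.
#' @return List with `features`, `model`, `evaluation`, invisibly.
#' @export
run_all <- function(config = pipeline_config(), out_dir,
                    compare_fssa = FALSE, keep_images = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (keep_images) {
    manifest <- run_simulate(config, file.path(out_dir, "images"))
    images <- NULL
  } else {
    ds <- generate_dataset(config$simulate, dir = NULL)
    manifest <- ds$manifest
    images <- ds$images
  }
  F <- run_extract(manifest, config, images = images,
                   out_csv = file.path(out_dir, "features.csv"))
  model <- run_train(F, config,
                     model_json = file.path(out_dir, "model.json"),
                     weights_csv = file.path(out_dir, "weights.csv"))
  evaluation <- run_evaluate(F, config, compare_fssa = compare_fssa,
                             out_json = file.path(out_dir, "metrics.json"))
  prov <- list(seed = config$seed,
               n_images = nrow(manifest),
               image_size = config$simulate$size,
               n_classes = config$simulate$n_classes,
               k = config$k,
               use_fssa = config$use_fssa,
               package_version = as.character(utils::packageVersion("quantex")))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(list(features = F, model = model, evaluation = evaluation))
}
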