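# Tiny separable binary fixture: one feature, class means 0.1 / 0.9.
sep_data <- function(n = 60, seed = 30) {
  set.seed(seed)
  y <- rep(0:1, n / 2)
  x <- ifelse(y == 1, 0.9, 0.1) + rnorm(n, 0, 0.05)
  list(X = matrix(pmin(1, pmax(0, x)), ncol = 1), y = y)
}

test_that("training energy is the definitional mean loss", {
  arch <- qdnn_architecture(2, 2)
  d <- list(X = matrix(runif(20), 10, 2), y = rep(0:1, 5))
  p0 <- qdnn_params(matrix(rnorm(4), 2, 2), c(0, 0))
  # V = 0 forces all predictions to 0.5: energy is ln 2
  expect_equal(qdnn_energy(p0, arch, d$X, d$y), log(2), tolerance = 1e-9)
  set.seed(31)
  p <- qdnn_params(matrix(rnorm(4), 2, 2), rnorm(2))
  expect_equal(qdnn_energy(p, arch, d$X, d$y),
               mean_loss(d$y, qdnn_forward_batch(d$X, arch, p)))
  expect_error(qdnn_energy(p, arch, d$X[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("SA training honors the zero budget and best-so-far contract", {
  arch <- qdnn_architecture(1, 1)
  d <- sep_data()
  cfg0 <- train_config(schedule = anneal_schedule(max_iter = 0), seed = 3)
  res0 <- train_sa(arch, d$X, d$y, cfg0)
  # untouched initialization
  init <- with_seed_helper(3, runif(2, -0.1, 0.1))
  expect_equal(as.vector(res0$params$W), init[1])
  expect_equal(res0$params$V, init[2])

  cfg <- train_config(schedule = anneal_schedule(max_iter = 150), seed = 3)
  res <- train_sa(arch, d$X, d$y, cfg)
  expect_true(all(diff(res$trace$best_energy) <= 0))
  expect_equal(qdnn_energy(res$params, arch, d$X, d$y), res$energy)
  expect_lte(res$energy, res0$energy)
})

test_that("SA training reduces the loss on separable data across seeds", {
  arch <- qdnn_architecture(1, 1)
  wins <- 0L
  for (s in 1:10) {
    d <- sep_data(seed = 100 + s)
    cfg0 <- train_config(schedule = anneal_schedule(max_iter = 0), seed = s)
    cfg <- train_config(schedule = anneal_schedule(max_iter = 300), seed = s)
    e0 <- train_sa(arch, d$X, d$y, cfg0)$energy
    e1 <- train_sa(arch, d$X, d$y, cfg)$energy
    if (e1 < e0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("SA training is bit-reproducible under a fixed seed", {
  arch <- qdnn_architecture(2, 1)
  d <- list(X = matrix(runif(40), 20, 2), y = rep(0:1, 10))
  cfg <- train_config(schedule = anneal_schedule(max_iter = 50), seed = 7)
  r1 <- train_sa(arch, d$X, d$y, cfg)
  r2 <- train_sa(arch, d$X, d$y, cfg)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$trace, r2$trace)
})

test_that("finite-difference gradient descent matches an exact trajectory", {
  # single readout weight, W pinned at zero: a = 0, yhat = sigmoid(0 * V)?
  # No: with W = 0 the prediction is 0.5 regardless of V, so use a direct
  # surrogate check instead — the central difference of the true energy.
  arch <- qdnn_architecture(1, 1)
  d <- sep_data(n = 20, seed = 40)
  cfg <- train_config(mode = "gd", lr = 0.5, epochs = 30, batch_size = 20,
                      seed = 9)
  res <- train_gd(arch, d$X, d$y, cfg)
  # exact reference: same updates computed here with numeric gradients
  theta <- with_seed_helper(9, runif(2, -0.1, 0.1))
  energy <- function(th)
    qdnn_energy(qdnn_params(matrix(th[1], 1, 1), th[2]), arch, d$X, d$y)
  h <- 1e-4
  set.seed(10)  # train_gd shuffles under seed + 1
  for (ep in 1:30) {
    ord <- sample(20)  # full batch: order irrelevant, but consume the RNG
    g <- vapply(1:2, function(k) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      (energy(tp) - energy(tm)) / (2 * h)
    }, numeric(1))
    theta <- theta - 0.5 * g
  }
  expect_equal(as.vector(res$params$W), theta[1], tolerance = 1e-10)
  expect_equal(res$params$V, theta[2], tolerance = 1e-10)
})

test_that("gradient mode converges on the separable fixture", {
  arch <- qdnn_architecture(1, 1)
  d <- sep_data(seed = 41)
  cfg0 <- train_config(mode = "gd", epochs = 1, lr = 1e-12, seed = 11)
  e0 <- train_gd(arch, d$X, d$y, cfg0)$energy  # effectively initial loss
  cfg <- train_config(mode = "gd", lr = 0.1, epochs = 50, batch_size = 32,
                      seed = 11)
  res <- train_gd(arch, d$X, d$y, cfg)
  expect_lt(res$energy, e0)
})

test_that("the multiclass fit selects features, scales, and predicts", {
  fm <- generate_feature_table(planted_config(n_samples = 120,
                                              k_informative = 4,
                                              m_noise = 4, effect = 4,
                                              seed = 50))
  arch <- qdnn_architecture(4, 2)
  cfg <- train_config(schedule = anneal_schedule(max_iter = 150), seed = 13)
  model <- fit_qdnn(fm, arch, cfg, use_fssa = TRUE,
                    fssa_cfg = fssa_config(
                      schedule = anneal_schedule(max_iter = 80), seed = 13))
  expect_s3_class(model, "qdnn_model")
  expect_length(model$heads, 4)
  expect_length(model$selected, 4)
  pred <- predict(model, fm)
  expect_length(pred$labels, 120)
  expect_equal(dim(pred$scores), c(120, 4))
  # planted classes: far above the 0.25 chance level on the training data,
  # even when the short selection budget captures only part of the signal
  expect_gt(mean(pred$labels == fm$labels), 0.4)
})

test_that("model JSON round-trips through write_model/read_model", {
  fm <- generate_feature_table(planted_config(n_samples = 60, seed = 51))
  arch <- qdnn_architecture(3, 1)
  model <- fit_qdnn(fm, arch,
                    train_config(schedule = anneal_schedule(max_iter = 20),
                                 seed = 1),
                    use_fssa = FALSE)
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$selected, model$selected)
  expect_equal(back$classes, model$classes)
  for (i in seq_along(model$heads)) {
    expect_equal(back$heads[[i]]$W, model$heads[[i]]$W, ignore_attr = TRUE)
    expect_equal(back$heads[[i]]$V, model$heads[[i]]$V)
  }
  p1 <- predict(model, fm)
  p2 <- predict(back, fm)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-12)
})
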