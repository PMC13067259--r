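test_that("uniform superposition has equal real amplitudes", {
  expect_equal(uniform_superposition(1), rep(1 / sqrt(2), 2))
  expect_equal(uniform_superposition(2), rep(0.5, 4))
  expect_equal(uniform_superposition(3), rep(1 / sqrt(8), 8))
  expect_error(uniform_superposition(0), "1..14")
  expect_error(uniform_superposition(15), "1..14")
})

test_that("Hadamard layer acts as the textbook gate and squares to identity", {
  expect_equal(hadamard_layer(c(1, 0), 1), c(1, 1) / sqrt(2))
  expect_equal(hadamard_layer(c(0, 1), 1), c(1, -1) / sqrt(2))
  set.seed(14)
  for (n in 2:4) {
    psi <- random_unit_state(n)
    q <- sample(n, 1)
    expect_equal(hadamard_layer(hadamard_layer(psi, q), q), psi,
                 tolerance = 1e-10)
    # matches the dense-matrix oracle
    expect_equal(hadamard_layer(psi, q),
                 as.vector(hadamard_matrix(q, n) %*% psi),
                 tolerance = 1e-12)
  }
  expect_error(hadamard_layer(c(1, 0), c(1, 1)), "duplicate")
  expect_error(hadamard_layer(c(1, 0), 3), "range")
})

test_that("amplitude encoding maps feature values to unit-norm qubits", {
  expect_equal(amplitude_encode(1), c(1, 0))
  expect_equal(amplitude_encode(0), c(0, 1))
  expect_equal(amplitude_encode(0.5), rep(1 / sqrt(2), 2))
  for (x in seq(0, 1, by = 0.1))
    expect_equal(sum(amplitude_encode(x)^2), 1)
  expect_error(amplitude_encode(1.2), "\\[0, 1\\]")
  expect_error(amplitude_encode(-0.1), "\\[0, 1\\]")
})

test_that("sample encoding is the msb-first tensor product", {
  expect_equal(encode_sample(c(1, 0)), c(0, 1, 0, 0))  # |01>
  expect_equal(encode_sample(c(0.5, 0.5)), rep(0.5, 4))
  expect_equal(encode_sample(c(0.25, 0.75)),
               c(sqrt(0.1875), sqrt(0.0625), sqrt(0.5625), sqrt(0.1875)))
})

test_that("the entangling layer is unitary and fixes W = 0", {
  set.seed(15)
  N <- 2L; M <- 2L; n <- N + M
  psi <- random_unit_state(n)
  expect_equal(apply_entangling_layer(psi, matrix(0, M, N), N, M), psi)

  W <- matrix(rnorm(M * N), M, N)
  out <- apply_entangling_layer(psi, W, N, M)
  expect_equal(sum(out^2), 1, tolerance = 1e-10)
  # inner products preserved between two random states
  phi <- random_unit_state(n)
  out2 <- apply_entangling_layer(phi, W, N, M)
  expect_equal(sum(out * out2), sum(psi * phi), tolerance = 1e-10)
  expect_error(apply_entangling_layer(psi, matrix(0, 3, 3), N, M), "M x N")
})

test_that("a satisfied control flips the target through R_y(pi)", {
  # input qubit |1>, hidden qubit |0>: W11 = pi rotates hidden to |1>
  psi <- as.vector(kronecker(c(0, 1), c(1, 0)))  # |10>
  out <- apply_entangling_layer(psi, matrix(pi, 1, 1), 1L, 1L)
  expect_equal(abs(out), c(0, 0, 0, 1), tolerance = 1e-12)
  # against the 4x4 dense oracle
  expect_equal(out, as.vector(cry_matrix(pi, 1, 2, 2) %*% psi),
               tolerance = 1e-12)
})

test_that("Z-expectations are exact amplitude sums", {
  expect_equal(measure_expectations(c(1, 0), 1), 1)
  expect_equal(measure_expectations(rep(1 / sqrt(2), 2), 1), 0)
  psi <- c(sqrt(0.3), sqrt(0.7))
  expect_equal(measure_expectations(psi, 1), -0.4)
  set.seed(16)
  psi4 <- random_unit_state(4)
  for (q in 1:4)
    expect_equal(measure_expectations(psi4, q), z_expect_oracle(psi4, q, 4),
                 tolerance = 1e-12)
})

test_that("forward collapses to 0.5 when either W or V vanishes", {
  arch <- qdnn_architecture(2, 2)
  set.seed(17)
  for (rep in 1:5) {
    x <- runif(2)
    pV0 <- qdnn_params(matrix(rnorm(4), 2, 2), c(0, 0))
    expect_equal(qdnn_forward(x, arch, pV0), 0.5)
    pW0 <- qdnn_params(matrix(0, 2, 2), rnorm(2))
    expect_equal(qdnn_forward(x, arch, pW0), 0.5)
  }
})

test_that("with W = 0 the prediction ignores the input features", {
  arch <- qdnn_architecture(3, 1)
  p <- qdnn_params(matrix(0, 1, 3), 0.7)
  expect_equal(qdnn_forward(c(0.1, 0.9, 0.3), arch, p),
               qdnn_forward(c(0.8, 0.2, 0.6), arch, p))
})

test_that("an engineered a = 1 head gives the closed-form prediction", {
  # one input fixed at x = 1 (|0>, control never satisfied): hidden stays
  # uniform... instead pin the hidden qubit by hand: a_1 = 1 requires the
  # hidden qubit in |0>; realize via x = 0 (control always on) and a
  # rotation that undoes the Hadamard superposition: R_y(-pi/2)|+> = |0>.
  arch <- qdnn_architecture(1, 1)
  p <- qdnn_params(matrix(-pi / 2, 1, 1), 2)
  yhat <- qdnn_forward(0, arch, p)
  expect_equal(yhat, 1 / (1 + exp(-2 * tanh(1))), tolerance = 1e-10)
  expect_equal(yhat, forward_oracle(0, matrix(-pi / 2, 1, 1), 2),
               tolerance = 1e-10)
})

test_that("forward agrees with the dense-matrix oracle for N + M <= 4", {
  set.seed(18)
  for (rep in 1:10) {
    N <- sample(1:3, 1); M <- sample(1:(4 - N), 1)
    x <- runif(N)
    W <- matrix(rnorm(M * N), M, N)
    V <- rnorm(M)
    arch <- qdnn_architecture(N, M)
    p <- qdnn_params(W, V)
    expect_equal(qdnn_forward(x, arch, p), forward_oracle(x, W, V),
                 tolerance = 1e-10)
  }
})

test_that("forward is deterministic and strictly inside (0, 1)", {
  arch <- qdnn_architecture(3, 2)
  set.seed(19)
  p <- qdnn_params(matrix(rnorm(6, 0, 3), 2, 3), rnorm(2, 0, 10))
  x <- runif(3)
  y1 <- qdnn_forward(x, arch, p)
  expect_identical(y1, qdnn_forward(x, arch, p))
  expect_gt(y1, 0)
  expect_lt(y1, 1)
})

test_that("batch forward equals the per-sample forward", {
  set.seed(20)
  arch <- qdnn_architecture(4, 2)
  p <- qdnn_params(matrix(rnorm(8), 2, 4), rnorm(2))
  X <- matrix(runif(40), 10, 4)
  expect_equal(qdnn_forward_batch(X, arch, p),
               apply(X, 1, function(x) qdnn_forward(x, arch, p)),
               tolerance = 1e-12)
})

test_that("binary cross-entropy takes its closed-form values", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(1, 1.0), 0, tolerance = 1e-10)
  expect_gte(bce_loss(0, 1.0), 0)  # clipped, finite
  expect_true(is.finite(bce_loss(0, 1.0)))
  expect_error(bce_loss(2, 0.5), "0 or 1")
})

test_that("mean loss is the arithmetic mean of per-sample losses", {
  expect_equal(mean_loss(c(1, 1), c(1, 0.5)), log(2) / 2, tolerance = 1e-9)
  expect_equal(mean_loss(c(0, 1), c(1e-13, 1 - 1e-13)), 0, tolerance = 1e-9)
  set.seed(21)
  y <- sample(0:1, 100, replace = TRUE)
  yh <- runif(100)
  expect_equal(mean_loss(y, yh), sum(bce_loss(y, yh)) / 100,
               tolerance = 1e-12)
  expect_error(mean_loss(numeric(0), numeric(0)), "empty")
})

test_that("multiclass argmax breaks ties toward the lowest class", {
  arch <- qdnn_architecture(2, 1)
  # heads engineered through V sign/size to order their outputs
  mk <- function(v) qdnn_params(matrix(pi / 2, 1, 2), v)
  x <- c(0.2, 0.2)
  scores <- vapply(c(-2, 2, 1, -1), function(v)
    qdnn_forward(x, arch, mk(v)), numeric(1))
  heads <- lapply(c(-2, 2, 1, -1), mk)
  expect_equal(predict_multiclass(x, arch, heads),
               which.max(scores) - 1L)
  same <- lapply(c(1, 1, 1), mk)
  expect_equal(predict_multiclass(x, arch, same), 0L)
  expect_error(predict_multiclass(x, arch, same[1]), "2 heads")
})

test_that("every state-producing operation preserves unit norm", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    psi <- random_unit_state(n)
    expect_equal(sum(hadamard_layer(psi, sample(n, 2))^2), 1,
                 tolerance = 1e-10)
    x <- runif(sample(1:4, 1))
    expect_equal(sum(encode_sample(x)^2), 1, tolerance = 1e-10)
  }
})
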