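# Hybrid quantum-classical classifier simulated exactly on a state vector.
#
# Register layout: N input qubits followed by M hidden qubits, qubit 1 most
# significant. A sample's scaled features are amplitude-encoded one per
# input qubit (sqrt(x)|0> + sqrt(1-x)|1>), the hidden register starts in the
# uniform superposition (Hadamard on |0...0>), and a layer of
# controlled-R_y(W[j, i]) gates (control: input qubit i on |1>, target:
# hidden qubit j) entangles the registers. The exact Z-expectations a_j of
# the hidden qubits are read out (no sampling noise), passed through tanh,
# combined with readout weights V, and squashed by a sigmoid into a
# predicted probability. All gates here are real, but the state operations
# accept complex amplitudes.

#' Network architecture
#'
#' @param N Input qubits, one amplitude-encoded feature each (>= 1).
#' @param M Hidden qubits (>= 1).
#' @param K Output qubits; fixed at 1 in binary mode and carried for
#'   bookkeeping only — the readout is classical.
#' @return A list of class `qdnn_architecture`.
#' @export
qdnn_architecture <- function(N, M, K = 1L) {
  N <- as.integer(N); M <- as.integer(M); K <- as.integer(K)
  if (N < 1L || M < 1L || K < 1L) stop("N, M and K must be >= 1")
  if (N + M > 14L)
    stop("N + M must not exceed 14 (state-vector size 2^(N+M))")
  structure(list(N = N, M = M, K = K, total_qubits = N + M + K),
            class = "qdnn_architecture")
}

#' Network parameters
#'
#' @param W `M x N` matrix of controlled-rotation angles (radians); `W[j, i]`
#'   connects input qubit `i` to hidden qubit `j`.
#' @param V Length-`M` vector of classical readout weights.
#' @return A list of class `qdnn_params`.
#' @export
qdnn_params <- function(W, V) {
  W <- as.matrix(W)
  if (!all(is.finite(W)) || !all(is.finite(V))) stop("parameters must be finite")
  if (nrow(W) != length(V))
    stop("nrow(W) must equal length(V) (one row and one readout per hidden qubit)")
  structure(list(W = W, V = as.numeric(V)), class = "qdnn_params")
}

# Bit value (0/1) of qubit q (1 = most significant) in each basis index of
# an n-qubit register; index i runs over 0..2^n-1 in amplitude order.
qubit_bit <- function(q, n) bitwAnd(bitwShiftR(0:(2^n - 1L), n - q), 1L)

check_state <- function(state) {
  n <- log2(length(state))
  if (length(state) < 2L || abs(n - round(n)) > 1e-9)
    stop("state length must be a power of two >= 2")
  as.integer(round(n))
}

#' Uniform superposition state
#'
#' All `2^n` amplitudes equal `1/sqrt(2^n)` — the result of a Hadamard on
#' every qubit of `|0...0>`.
#'
#' @param n_qubits Register size, 1..14.
#' @return Numeric amplitude vector of length `2^n_qubits`.
#' @export
uniform_superposition <- function(n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (is.na(n_qubits) || n_qubits < 1L || n_qubits > 14L)
    stop("`n_qubits` must be in 1..14")
  rep(1 / sqrt(2^n_qubits), 2^n_qubits)
}

#' Apply Hadamard gates to selected qubits
#'
#' @param state Amplitude vector over a `2^n` register (real or complex).
#' @param qubits Distinct qubit indices (1 = most significant).
#' @return The transformed amplitude vector.
#' @export
hadamard_layer <- function(state, qubits) {
  n <- check_state(state)
  qubits <- as.integer(qubits)
  if (anyDuplicated(qubits)) stop("duplicate qubit index")
  if (any(qubits < 1L | qubits > n)) stop("qubit index out of range")
  for (q in qubits) {
    bit <- qubit_bit(q, n)
    i0 <- which(bit == 0L)
    i1 <- i0 + 2L^(n - q)
    a0 <- state[i0]; a1 <- state[i1]
    state[i0] <- (a0 + a1) / sqrt(2)
    state[i1] <- (a0 - a1) / sqrt(2)
  }
  state
}

#' Amplitude-encode one scaled feature on a single qubit
#'
#' Maps a feature value `x` in `[0, 1]` to the qubit state
#' `sqrt(x)|0> + sqrt(1 - x)|1>`, i.e. `x` is the probability of reading 0.
#'
#' @param x Scaled feature value in `[0, 1]`.
#' @return Length-2 amplitude vector `(sqrt(x), sqrt(1 - x))`.
#' @export
amplitude_encode <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("feature value must lie in [0, 1]; scale features first")
  c(sqrt(x), sqrt(1 - x))
}

#' Encode a feature vector as a product state
#'
#' Tensor product of the per-feature single-qubit encodings, feature 1 on
#' the most significant qubit.
#'
#' @param features Numeric vector of `N` values in `[0, 1]`.
#' @return Amplitude vector of length `2^N` with unit norm.
#' @export
encode_sample <- function(features) {
  if (length(features) < 1L) stop("need at least one feature")
  state <- 1
  for (x in features) state <- kronecker(state, amplitude_encode(x))
  as.vector(state)
}

#' Apply the controlled-rotation entangling layer
#'
#' For each input qubit `i` (ascending) and hidden qubit `j` (ascending),
#' applies a controlled-`R_y(W[j, i])` with control on input qubit `i`
#' being `|1>` and target hidden qubit `j`. Unitary; `W = 0` leaves the
#' state unchanged.
#'
#' @param state Amplitude vector over `N + M` qubits (inputs first).
#' @param W `M x N` angle matrix.
#' @param N,M Input and hidden register sizes.
#' @return The transformed amplitude vector.
#' @export
apply_entangling_layer <- function(state, W, N, M) {
  n <- check_state(state)
  if (n != N + M) stop("state register must hold N + M qubits")
  W <- as.matrix(W)
  if (nrow(W) != M || ncol(W) != N) stop("W must be an M x N matrix")
  for (i in seq_len(N)) {
    ctrl <- qubit_bit(i, n)
    for (j in seq_len(M)) {
      theta <- W[j, i]
      if (theta == 0) next
      tgt <- N + j
      bit <- qubit_bit(tgt, n)
      i0 <- which(ctrl == 1L & bit == 0L)
      i1 <- i0 + 2L^(n - tgt)
      c2 <- cos(theta / 2); s2 <- sin(theta / 2)
      a0 <- state[i0]; a1 <- state[i1]
      state[i0] <- c2 * a0 - s2 * a1
      state[i1] <- s2 * a0 + c2 * a1
    }
  }
  state
}

#' Exact Z-expectations of selected qubits
#'
#' `a_q = P(qubit q reads 0) - P(qubit q reads 1)`, computed from the
#' amplitudes with no sampling.
#'
#' @param state Amplitude vector.
#' @param qubits Qubit indices to measure.
#' @return Numeric vector of expectations in `[-1, 1]`.
#' @export
measure_expectations <- function(state, qubits) {
  n <- check_state(state)
  prob <- Mod(state)^2
  vapply(as.integer(qubits), function(q) {
    if (q < 1L || q > n) stop("qubit index out of range")
    bit <- qubit_bit(q, n)
    sum(prob[bit == 0L]) - sum(prob[bit == 1L])
  }, numeric(1))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the classifier
#'
#' Pipeline: amplitude-encode the features on the input register, put the
#' hidden register into the uniform superposition, entangle with
#' controlled rotations, read the exact hidden Z-expectations `a_j`, and
#' output `sigmoid(sum_j V[j] * tanh(a_j))`. Deterministic; the output lies
#' strictly inside `(0, 1)`.
#'
#' @param features Length-`N` scaled feature vector in `[0, 1]`.
#' @param arch A [qdnn_architecture()].
#' @param params A [qdnn_params()].
#' @return Predicted probability.
#' @export
qdnn_forward <- function(features, arch, params) {
  stopifnot(inherits(arch, "qdnn_architecture"), inherits(params, "qdnn_params"))
  if (length(features) != arch$N)
    stop("expected ", arch$N, " features, got ", length(features))
  if (nrow(params$W) != arch$M || ncol(params$W) != arch$N)
    stop("parameter shapes do not match the architecture")
  state <- as.vector(kronecker(encode_sample(features),
                               uniform_superposition(arch$M)))
  state <- apply_entangling_layer(state, params$W, arch$N, arch$M)
  a <- measure_expectations(state, arch$N + seq_len(arch$M))
  o <- sum(params$V * tanh(a))
  sigmoid(o)
}

#' Vectorized forward pass over a sample matrix
#'
#' Same computation as [qdnn_forward()], carried out on all rows of a
#' feature matrix at once (states held as a samples-by-amplitudes matrix).
#'
#' @param X Numeric matrix, one scaled sample per row, `N` columns.
#' @param arch A [qdnn_architecture()].
#' @param params A [qdnn_params()].
#' @return Vector of predicted probabilities, one per row.
#' @export
qdnn_forward_batch <- function(X, arch, params) {
  stopifnot(inherits(arch, "qdnn_architecture"), inherits(params, "qdnn_params"))
  X <- as.matrix(X)
  if (ncol(X) != arch$N)
    stop("expected ", arch$N, " feature columns, got ", ncol(X))
  if (any(X < 0) || any(X > 1)) stop("features must lie in [0, 1]")
  n_s <- nrow(X)
  N <- arch$N; M <- arch$M; n <- N + M
  # input product states, feature 1 most significant
  S <- matrix(1, n_s, 1L)
  for (i in seq_len(N)) {
    a0 <- sqrt(X[, i]); a1 <- sqrt(1 - X[, i])
    S <- S[, rep(seq_len(ncol(S)), each = 2L), drop = FALSE] *
      cbind(a0, a1)[, rep(1:2, ncol(S)), drop = FALSE]
  }
  # hidden register in uniform superposition
  S <- S[, rep(seq_len(2^N), each = 2^M), drop = FALSE] / sqrt(2^M)
  # entangling layer, (i ascending, j ascending)
  for (i in seq_len(N)) {
    ctrl <- qubit_bit(i, n)
    for (j in seq_len(M)) {
      theta <- params$W[j, i]
      if (theta == 0) next
      tgt <- N + j
      bit <- qubit_bit(tgt, n)
      i0 <- which(ctrl == 1L & bit == 0L)
      i1 <- i0 + 2L^(n - tgt)
      c2 <- cos(theta / 2); s2 <- sin(theta / 2)
      a0 <- S[, i0, drop = FALSE]; a1 <- S[, i1, drop = FALSE]
      S[, i0] <- c2 * a0 - s2 * a1
      S[, i1] <- s2 * a0 + c2 * a1
    }
  }
  P <- S^2
  o <- numeric(n_s)
  for (j in seq_len(M)) {
    bit <- qubit_bit(N + j, n)
    a_j <- rowSums(P[, bit == 0L, drop = FALSE]) -
      rowSums(P[, bit == 1L, drop = FALSE])
    o <- o + params$V[j] * tanh(a_j)
  }
  sigmoid(o)
}

#' Binary cross-entropy loss
#'
#' `-(y * ln(yh) + (1 - y) * ln(1 - yh))` with the prediction clipped to
#' `[1e-12, 1 - 1e-12]` so the loss is finite for degenerate predictions.
#'
#' @param y True label, 0 or 1 (vectorized).
#' @param y_hat Predicted probability (vectorized).
#' @return Loss value(s), >= 0.
#' @export
bce_loss <- function(y, y_hat) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  yh <- pmin(1 - 1e-12, pmax(1e-12, y_hat))
  -(y * log(yh) + (1 - y) * log(1 - yh))
}

#' Mean binary cross-entropy over a batch
#'
#' @param labels 0/1 label vector.
#' @param predictions Predicted probabilities, same length.
#' @return Arithmetic mean of the per-sample losses.
#' @export
mean_loss <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  mean(bce_loss(labels, predictions))
}

#' Multiclass prediction by one-vs-rest heads
#'
#' Runs every binary head on the sample and returns the class index
#' (0-based) of the largest predicted probability; ties break to the lowest
#' index.
#'
#' @param features Scaled feature vector.
#' @param arch Shared [qdnn_architecture()].
#' @param heads List of [qdnn_params()], one per class.
#' @return 0-based class index.
#' @export
predict_multiclass <- function(features, arch, heads) {
  if (length(heads) < 2L) stop("need at least 2 heads")
  scores <- vapply(heads, function(h) qdnn_forward(features, arch, h),
                   numeric(1))
  which.max(scores) - 1L
}
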