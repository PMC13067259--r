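# Independent oracles used across the suite. These are deliberately naive
# (double loops, dense matrices) and never share code with the package
# implementation they check.

# Brute-force GLCM: count pixel pairs with an explicit double loop.
brute_glcm <- function(img, dr, dc, L, symmetric = TRUE) {
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        i <- img[r, cc] + 1L; j <- img[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# (row, col) offset of the four standard GLCM directions.
oracle_offset <- function(d, theta) {
  if (theta == 0) c(0L, d)
  else if (isTRUE(all.equal(theta, pi / 4))) c(-d, d)
  else if (isTRUE(all.equal(theta, pi / 2))) c(-d, 0L)
  else c(-d, -d)
}

# --- dense-matrix quantum gate oracle -------------------------------------

single_qubit_matrix <- function(U2, q, n) {
  left <- diag(2^(q - 1))
  right <- diag(2^(n - q))
  kronecker(kronecker(left, U2), right)
}

hadamard_matrix <- function(q, n) {
  H2 <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  single_qubit_matrix(H2, q, n)
}

# Controlled-R_y(theta): control qubit `ctrl` on |1>, target `tgt`.
cry_matrix <- function(theta, ctrl, tgt, n) {
  U <- matrix(0, 2^n, 2^n)
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  for (b in 0:(2^n - 1)) {
    cbit <- bitwAnd(bitwShiftR(b, n - ctrl), 1L)
    if (cbit == 0L) {
      U[b + 1, b + 1] <- 1
    } else {
      tbit <- bitwAnd(bitwShiftR(b, n - tgt), 1L)
      b0 <- b - tbit * 2^(n - tgt)
      b1 <- b0 + 2^(n - tgt)
      if (tbit == 0L) {       # column of |...0...>
        U[b0 + 1, b + 1] <- c2
        U[b1 + 1, b + 1] <- s2
      } else {                # column of |...1...>
        U[b0 + 1, b + 1] <- -s2
        U[b1 + 1, b + 1] <- c2
      }
    }
  }
  U
}

z_expect_oracle <- function(psi, q, n) {
  signs <- 1 - 2 * bitwAnd(bitwShiftR(0:(2^n - 1), n - q), 1L)
  sum(signs * Mod(psi)^2)
}

# Full forward pass built from dense matrices only.
forward_oracle <- function(features, W, V) {
  N <- length(features); M <- length(V); n <- N + M
  psi_in <- 1
  for (x in features) psi_in <- kronecker(psi_in, c(sqrt(x), sqrt(1 - x)))
  hid0 <- c(1, rep(0, 2^M - 1))
  psi <- kronecker(psi_in, hid0)
  for (j in seq_len(M)) psi <- hadamard_matrix(N + j, n) %*% psi
  for (i in seq_len(N)) for (j in seq_len(M))
    psi <- cry_matrix(W[j, i], i, N + j, n) %*% psi
  a <- vapply(seq_len(M), function(j) z_expect_oracle(psi, N + j, n),
              numeric(1))
  1 / (1 + exp(-sum(V * tanh(a))))
}

random_unit_state <- function(n_qubits) {
  v <- stats::rnorm(2^n_qubits)
  v / sqrt(sum(v^2))
}

# Evaluate expr after seeding, mirroring a seeded draw without relying on
# package internals.
with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}
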