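# Independent reference implementations used as oracles. These are
# deliberately written as plain loops, separate from the package's
# vectorised code paths.

# Eq-by-eq spatial attention: P = Vp sigmoid((X Z1) Z2 (Z3 X)' + bp),
# row-softmax, everything as explicit loops.
oracle_spatial_attention <- function(X, p) {
  d <- dim(X); N <- d[1]; C <- d[2]; T <- d[3]
  A1 <- matrix(0, N, C)
  for (n in 1:N) for (c in 1:C) A1[n, c] <- sum(X[n, c, ] * p$Z1)
  A2 <- matrix(0, N, T)
  for (n in 1:N) for (t in 1:T) A2[n, t] <- sum(A1[n, ] * p$Z2[, t])
  A3 <- matrix(0, N, T)
  for (n in 1:N) for (t in 1:T) A3[n, t] <- sum(p$Z3 * X[n, , t])
  E <- matrix(0, N, N)
  for (m in 1:N) for (n in 1:N) E[m, n] <- sum(A2[m, ] * A3[n, ])
  S <- 1 / (1 + exp(-(E + p$bp)))
  P <- matrix(0, N, N)
  for (m in 1:N) for (n in 1:N) P[m, n] <- sum(p$Vp[m, ] * S[, n])
  out <- matrix(0, N, N)
  for (m in 1:N) {
    e <- exp(P[m, ] - max(P[m, ]))
    out[m, ] <- e / sum(e)
  }
  out
}

oracle_temporal_attention <- function(X, q) {
  d <- dim(X); N <- d[1]; C <- d[2]; T <- d[3]
  B1 <- matrix(0, T, C)
  for (t in 1:T) for (c in 1:C) B1[t, c] <- sum(X[, c, t] * q$M1)
  B2 <- matrix(0, T, N)
  for (t in 1:T) for (n in 1:N) B2[t, n] <- sum(B1[t, ] * q$M2[, n])
  B3 <- matrix(0, N, T)
  for (n in 1:N) for (t in 1:T) B3[n, t] <- sum(q$M3 * X[n, , t])
  E <- matrix(0, T, T)
  for (u in 1:T) for (v in 1:T) E[u, v] <- sum(B2[u, ] * B3[, v])
  S <- 1 / (1 + exp(-(E + q$bq)))
  Q <- matrix(0, T, T)
  for (u in 1:T) for (v in 1:T) Q[u, v] <- sum(q$Vq[u, ] * S[, v])
  out <- matrix(0, T, T)
  for (u in 1:T) {
    e <- exp(Q[u, ] - max(Q[u, ]))
    out[u, ] <- e / sum(e)
  }
  out
}

# Dense Chebyshev spectral filter per input/output channel pair:
# y = sum_k Theta[k, ci, co] T_k(L) x  (no attention modulation, no ReLU).
oracle_dense_cheb_filter <- function(X, L_tilde, Theta) {
  d <- dim(X); N <- d[1]; Cin <- d[2]; T <- d[3]
  K <- dim(Theta)[1]; Cout <- dim(Theta)[3]
  Tk <- vector("list", K)
  Tk[[1]] <- diag(N)
  if (K >= 2) Tk[[2]] <- L_tilde
  if (K >= 3) for (k in 3:K)
    Tk[[k]] <- 2 * L_tilde %*% Tk[[k - 1]] - Tk[[k - 2]]
  out <- array(0, c(N, Cout, T))
  for (t in 1:T) for (co in 1:Cout) for (ci in 1:Cin) for (k in 1:K) {
    out[, co, t] <- out[, co, t] +
      Theta[k, ci, co] * drop(Tk[[k]] %*% X[, ci, t])
  }
  out
}

# Sliding-window temporal convolution (same padding), triple loop.
oracle_temporal_conv <- function(X, Phi) {
  d <- dim(X); N <- d[1]; Cin <- d[2]; T <- d[3]
  kt <- dim(Phi)[1]; Cout <- dim(Phi)[3]
  pad <- (kt - 1) %/% 2
  out <- array(0, c(N, Cout, T))
  for (n in 1:N) for (co in 1:Cout) for (t in 1:T) {
    acc <- 0
    for (tau in 1:kt) for (ci in 1:Cin) {
      ts <- t + tau - 1 - pad
      if (ts >= 1 && ts <= T) acc <- acc + Phi[tau, ci, co] * X[n, ci, ts]
    }
    out[n, co, t] <- max(acc, 0)
  }
  out
}

# Direct Eq-1 evaluation for a single feature matrix.
oracle_fc_adjacency <- function(X, w) {
  N <- nrow(X)
  A <- matrix(0, N, N)
  for (m in 1:N) for (n in 1:N)
    A[m, n] <- exp(max(sum(w * abs(X[m, ] - X[n, ])), 0))
  A / rowSums(A)
}

# Brute-force double sum of the graph-learning loss.
oracle_graph_loss <- function(X, A, lambda) {
  N <- nrow(X)
  acc <- 0
  for (m in 1:N) for (n in 1:N)
    acc <- acc + sum((X[m, ] - X[n, ])^2) * A[m, n]
  acc + lambda * sum(A^2)
}
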