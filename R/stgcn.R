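#' Attention-modulated Chebyshev graph convolution
#'
#' Per timestep, `out[, , t] = ReLU( sum_k (T_k(L_tilde) * P') X[, , t] Theta_k )`
#' where `*` is the elementwise product: the spatial attention map `P'`
#' modulates each Chebyshev aggregation matrix, so attention dynamically
#' adjusts how much each neighbour contributes while the Laplacian
#' polynomial fixes which neighbours are reachable. With `P'` set to the
#' all-ones matrix this reduces to the textbook Chebyshev spectral filter.
#'
#' @param X Layer input `[N x C_in x T]` (typically already mixed by
#'   temporal attention).
#' @param cheb List of K matrices from [cheb_polynomials()].
#' @param Theta Filter tensor `[K x C_in x C_out]`.
#' @param P_prime Spatial attention `[N x N]`; all-ones disables modulation.
#' @param activation Apply the inner ReLU (default TRUE).
#' @return Array `[N x C_out x T]`.
#' @export
cheb_graph_conv <- function(X, cheb, Theta, P_prime = NULL, activation = TRUE) {
  d <- dim(X)
  K <- length(cheb)
  dt <- dim(Theta)
  if (length(dt) != 3L || dt[1] != K)
    stopf("Theta must be [K=%d x C_in x C_out]", K)
  if (dt[2] != d[2])
    stopf("Theta input channels (%d) do not match X channels (%d)", dt[2], d[2])
  if (is.null(P_prime)) P_prime <- matrix(1, d[1], d[1])
  out <- array(0, c(d[1], dt[3], d[3]))
  G <- lapply(seq_len(K), function(k) cheb[[k]] * P_prime)
  for (t in seq_len(d[3])) {
    Xt <- matrix(X[, , t], d[1], d[2])
    acc <- matrix(0, d[1], dt[3])
    for (k in seq_len(K)) {
      Th <- matrix(Theta[k, , ], dt[2], dt[3])
      acc <- acc + (G[[k]] %*% Xt) %*% Th
    }
    out[, , t] <- acc
  }
  if (activation) out <- relu(out)
  out
}

#' Temporal convolution over the context window
#'
#' A same-padded 1-D convolution along the temporal axis applied
#' identically at every node, mixing channels, followed by ReLU. This is
#' the standard 2-D convolution of the spatial-temporal block restricted
#' to its (node-preserving) temporal footprint: it captures transition
#' structure between neighbouring sleep epochs.
#'
#' @param X Array `[N x C_in x T]`.
#' @param Phi Kernel tensor `[k_t x C_in x C_out]`, `k_t` odd and `<= T`.
#' @param activation Apply ReLU (default TRUE).
#' @return Array `[N x C_out x T]`.
#' @export
temporal_conv <- function(X, Phi, activation = TRUE) {
  d <- dim(X)
  dp <- dim(Phi)
  if (length(dp) != 3L) stopf("Phi must be [k_t x C_in x C_out]")
  kt <- dp[1]
  if (kt %% 2L == 0L) stopf("temporal kernel length k_t must be odd")
  if (kt > d[3]) stopf("kernel length k_t = %d exceeds T = %d", kt, d[3])
  if (dp[2] != d[2]) stopf("Phi input channels (%d) != X channels (%d)", dp[2], d[2])
  pad <- (kt - 1L) %/% 2L
  Xp <- array(0, c(d[1], d[2], d[3] + 2L * pad))
  Xp[, , pad + seq_len(d[3])] <- X
  out <- array(0, c(d[1], dp[3], d[3]))
  for (tau in seq_len(kt)) {
    sl <- Xp[, , (tau - 1L) + seq_len(d[3]), drop = FALSE]
    # contract channels: [N*T x C_in] %*% [C_in x C_out]
    M <- matrix(aperm(sl, c(1L, 3L, 2L)), nrow = d[1] * d[3], ncol = d[2])
    R <- M %*% matrix(Phi[tau, , ], dp[2], dp[3])
    out <- out + aperm(array(R, c(d[1], d[3], dp[3])), c(1L, 3L, 2L))
  }
  if (activation) out <- relu(out)
  out
}

#' Fuse the two view branches
#'
#' Concatenates branch outputs along the channel axis without mixing;
#' slicing the result recovers both inputs exactly.
#'
#' @param X_fc,X_dc Arrays `[N x C x T]` sharing node and temporal dims.
#' @return Array `[N x (C_fc + C_dc) x T]`.
#' @export
fuse_views <- function(X_fc, X_dc) {
  d1 <- dim(X_fc); d2 <- dim(X_dc)
  if (d1[1] != d2[1] || d1[3] != d2[3])
    stopf("branch outputs disagree on node/temporal dims: [%s] vs [%s]",
          paste(d1, collapse = "x"), paste(d2, collapse = "x"))
  out <- array(0, c(d1[1], d1[2] + d2[2], d1[3]))
  out[, seq_len(d1[2]), ] <- X_fc
  out[, d1[2] + seq_len(d2[2]), ] <- X_dc
  out
}
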