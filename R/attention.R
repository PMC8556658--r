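#' Initialize spatial attention parameters
#'
#' Parameters for the spatial attention map over a layer input
#' `[N x C x T]`: `Vp, bp [N x N]`, `Z1 [T]`, `Z2 [C x T]`, `Z3 [C]`.
#' All start uniform in `+-eps` so the initial attention is near-uniform
#' and the sigmoid is unsaturated.
#'
#' @param N,C,T Layer-input dimensions.
#' @param eps Initialization half-width, default 1e-2.
#' @return A list of class `sg_spatial_attention`.
#' @export
init_spatial_attention <- function(N, C, T, eps = 1e-2) {
  structure(list(Vp = small_uniform(c(N, N), eps),
                 bp = small_uniform(c(N, N), eps),
                 Z1 = small_uniform(T, eps),
                 Z2 = small_uniform(c(C, T), eps),
                 Z3 = small_uniform(C, eps)),
            class = "sg_spatial_attention")
}

#' Initialize temporal attention parameters
#'
#' `Vq, bq [T x T]`, `M1 [N]`, `M2 [C x N]`, `M3 [C]`.
#'
#' @inheritParams init_spatial_attention
#' @return A list of class `sg_temporal_attention`.
#' @export
init_temporal_attention <- function(N, C, T, eps = 1e-2) {
  structure(list(Vq = small_uniform(c(T, T), eps),
                 bq = small_uniform(c(T, T), eps),
                 M1 = small_uniform(N, eps),
                 M2 = small_uniform(c(C, N), eps),
                 M3 = small_uniform(C, eps)),
            class = "sg_temporal_attention")
}

#' Spatial attention map
#'
#' `P = Vp . sigmoid((X Z1) Z2 (Z3 X)' + bp)`, normalized by a row-wise
#' softmax to `P'`; `P'[m, n]` weights how much node n contributes to the
#' update of node m during graph convolution.
#'
#' @param X Layer input array `[N x C x T]`.
#' @param p Parameters from [init_spatial_attention()].
#' @return Row-stochastic matrix `P'` `[N x N]`.
#' @export
spatial_attention <- function(X, p) {
  d <- dim(X)
  check_attention_shapes(d, length(p$Z1), dim(p$Z2), length(p$Z3),
                         dim(p$Vp), "spatial")
  A1 <- apply(X, c(1L, 2L), function(v) sum(v * p$Z1))   # [N x C]
  A2 <- A1 %*% p$Z2                                      # [N x T]
  A3 <- apply(X, c(1L, 3L), function(v) sum(v * p$Z3))   # [N x T]
  P <- p$Vp %*% sigmoid(A2 %*% t(A3) + p$bp)
  row_softmax(P)
}

#' Temporal attention map
#'
#' `Q = Vq . sigmoid((X' M1) M2 (M3 X) + bq)` with row-softmax
#' normalization; `Q'[u, v]` weights how much epoch u of the context
#' window draws on epoch v.
#'
#' @param X Layer input array `[N x C x T]`.
#' @param q Parameters from [init_temporal_attention()].
#' @return Row-stochastic matrix `Q'` `[T x T]`.
#' @export
temporal_attention <- function(X, q) {
  d <- dim(X)
  if (length(q$M1) != d[1] || !all(dim(q$M2) == c(d[2], d[1])) ||
      length(q$M3) != d[2] || !all(dim(q$Vq) == c(d[3], d[3])))
    stopf("temporal attention shape mismatch: input [N=%d x C=%d x T=%d]",
          d[1], d[2], d[3])
  B1 <- apply(X, c(3L, 2L), function(v) sum(v * q$M1))   # [T x C]
  B2 <- B1 %*% q$M2                                      # [T x N]
  B3 <- apply(X, c(1L, 3L), function(v) sum(v * q$M3))   # [N x T]
  Q <- q$Vq %*% sigmoid(B2 %*% B3 + q$bq)
  row_softmax(Q)
}

#' Mix a layer input along time with a temporal attention map
#'
#' `Xhat[, , t] = sum_u X[, , u] Q'[u, t]` (matrix product along the
#' temporal mode); the identity map leaves X unchanged and a uniform map
#' replaces every timestep by the temporal mean.
#'
#' @param X Array `[N x C x T]`.
#' @param Q_prime `[T x T]` mixing matrix (row-stochastic in normal use).
#' @return Array of the same shape as `X`.
#' @export
apply_temporal_attention <- function(X, Q_prime) {
  d <- dim(X)
  if (!all(dim(Q_prime) == c(d[3], d[3])))
    stopf("Q' must be [%d x %d]", d[3], d[3])
  rs <- rowSums(Q_prime)
  if (max(abs(rs - 1)) > 1e-6)
    warnf("Q' rows do not sum to 1 (max deviation %.2g)", max(abs(rs - 1)))
  M <- matrix(X, nrow = d[1] * d[2], ncol = d[3])
  array(M %*% Q_prime, dim = d)
}

check_attention_shapes <- function(d, lz1, dz2, lz3, dvp, what) {
  if (lz1 != d[3] || !all(dz2 == c(d[2], d[3])) || lz3 != d[2] ||
      !all(dvp == c(d[1], d[1])))
    stopf("%s attention shape mismatch: input [N=%d x C=%d x T=%d]",
          what, d[1], d[2], d[3])
}
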