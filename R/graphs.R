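#' Learn the functional-connectivity adjacency from node features
#'
#' The adjacency between channels m and n is a one-layer network of the
#' absolute feature difference:
#' `A[m, n] = softmax_n( ReLU( w' |x_m - x_n| ) )`,
#' normalised per row, so every row of the result sums to 1 and all entries
#' lie in (0, 1]. Identical node features (or `w = 0`) give the uniform
#' matrix `1/N`.
#'
#' @param X Feature matrix `[N x Fd]` (finite).
#' @param w Learnable weight vector, length Fd.
#' @return Row-stochastic adjacency `[N x N]`.
#' @export
learn_fc_adjacency <- function(X, w) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("non-finite entries in feature matrix")
  if (length(w) != ncol(X))
    stopf("w has length %d but Fd = %d", length(w), ncol(X))
  N <- nrow(X)
  logits <- matrix(0, N, N)
  for (m in seq_len(N)) {
    D <- abs(sweep(X, 2L, X[m, ]))            # |x_n - x_m| rows
    logits[m, ] <- pmax(D %*% w, 0)
  }
  row_softmax(logits)
}

#' Graph-learning loss
#'
#' Sum of squared feature distances weighted by the adjacency, plus a
#' Frobenius penalty controlling sparsity:
#' `sum_{m,n} ||x_m - x_n||^2 A[m,n] + lambda * ||A||_F^2`.
#' Used as a regularized term of the training objective so the adjacency
#' weights cannot collapse to the trivial solution.
#'
#' @param X Feature matrix `[N x Fd]`.
#' @param A Row-stochastic adjacency from [learn_fc_adjacency()].
#' @param lambda_reg Regularization weight, default 0.001.
#' @return Non-negative scalar.
#' @export
graph_learning_loss <- function(X, A, lambda_reg = 0.001) {
  if (lambda_reg < 0) stopf("lambda_reg must be non-negative")
  X <- as.matrix(X)
  D2 <- as.matrix(stats::dist(X))^2
  sum(D2 * A) + lambda_reg * sum(A^2)
}

#' Physical-distance brain graph
#'
#' Edge weights decay with squared Euclidean distance between electrode
#' positions through a Gaussian kernel
#' `A[m, n] = exp(-||c_m - c_n||^2 / (2 sigma^2))` for `m != n`, so the
#' weight is inversely related to physical distance. Entries below
#' `threshold` are cut to zero; the diagonal is zero and the matrix is
#' symmetric.
#'
#' @param montage An [sg_montage] with at least 2 channels.
#' @param sigma Kernel width; default is the mean pairwise distance.
#' @param threshold Cut-off in `[0, 1)`; default 0.1.
#' @return Symmetric non-negative adjacency `[N x N]` with zero diagonal.
#' @export
build_distance_adjacency <- function(montage, sigma = NULL, threshold = 0.1) {
  stopifnot(inherits(montage, "sg_montage"))
  C <- montage$coords
  N <- nrow(C)
  if (N < 2L) stopf("need at least 2 channels")
  if (threshold < 0 || threshold >= 1) stopf("threshold must be in [0, 1)")
  Dm <- as.matrix(stats::dist(C))
  if (any(Dm[upper.tri(Dm)] < 1e-12))
    warnf("duplicate electrode coordinates: coincident channels get edge weight 1")
  if (is.null(sigma)) sigma <- mean(Dm[upper.tri(Dm)])
  if (sigma <= 0) stopf("sigma must be positive")
  A <- exp(-Dm^2 / (2 * sigma^2))
  A[A < threshold] <- 0
  diag(A) <- 0
  if (all(A == 0))
    warnf("distance graph has no edges at threshold %g (disconnected)", threshold)
  dimnames(A) <- list(montage$names, montage$names)
  A
}

#' Scaled graph Laplacian
#'
#' `L = D - A` with `D = diag(row sums)`, rescaled to
#' `L_tilde = (2 / lambda_max) L - I` so the spectrum lies in `[-1, 1]`,
#' as required by the Chebyshev expansion. Asymmetric input is symmetrized
#' as `(A + A') / 2` first. An all-zero graph has `lambda_max = 0`; the
#' fallback `lambda_max := 2` returns `-I` with a warning.
#'
#' @param A Square non-negative adjacency.
#' @return List-free matrix `L_tilde` with attribute `"lambda_max"`.
#' @export
scaled_laplacian <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stopf("adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-12) A <- (A + t(A)) / 2
  L <- diag(rowSums(A)) - A
  lmax <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax <= 1e-12) {
    warnf("all-zero graph: falling back to lambda_max = 2 (L_tilde = -I)")
    lmax <- 2
  }
  Lt <- (2 / lmax) * L - diag(nrow(A))
  attr(Lt, "lambda_max") <- lmax
  Lt
}

#' Chebyshev polynomial basis of the scaled Laplacian
#'
#' `T_0 = I`, `T_1 = L_tilde`, `T_k = 2 L_tilde T_{k-1} - T_{k-2}`. A
#' degree K-1 expansion aggregates information from 0..K-1-hop neighbours.
#'
#' @param L_tilde Scaled Laplacian (spectral radius <= 1 + 1e-6).
#' @param K Number of polynomials (>= 1).
#' @return List of K matrices.
#' @export
cheb_polynomials <- function(L_tilde, K) {
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  L_tilde <- as.matrix(L_tilde)
  N <- nrow(L_tilde)
  out <- vector("list", K)
  out[[1]] <- diag(N)
  if (K >= 2L) out[[2]] <- L_tilde
  if (K >= 3L) for (k in 3:K)
    out[[k]] <- 2 * L_tilde %*% out[[k - 1]] - out[[k - 2]]
  out
}

#' Fixed functional-connectivity baselines
#'
#' Non-adaptive adjacency constructions used as comparison graphs:
#' \describe{
#'   \item{full}{all-ones matrix (every pair connected, self-loops kept).}
#'   \item{knn}{per row, the k most similar neighbours (by absolute
#'     Pearson correlation) get weight 1; symmetrized by `max(A, A')`.}
#'   \item{pcc}{absolute Pearson correlation per channel pair.}
#'   \item{plv}{phase-locking value: modulus of the mean unit phasor of
#'     the instantaneous (analytic-signal) phase difference.}
#'   \item{mi}{histogram mutual information per pair
#'     (equal-width, `ceiling(sqrt(Ts))` bins), min-max scaled to [0, 1].}
#' }
#'
#' @param method One of `"full"`, `"knn"`, `"pcc"`, `"plv"`, `"mi"`.
#' @param data Channel-by-time matrix `[N x Ts]` (required except for
#'   `"full"`, where only the channel count is needed).
#' @param n Number of channels (for `"full"` without data).
#' @param k Neighbours for `"knn"` (must be < N).
#' @return Symmetric adjacency `[N x N]`.
#' @export
fixed_adjacency <- function(method = c("full", "knn", "pcc", "plv", "mi"),
                            data = NULL, n = NULL, k = 2L) {
  method <- match.arg(method)
  if (method == "full") {
    N <- n %||% nrow(data)
    return(matrix(1, N, N))
  }
  data <- as.matrix(data)
  N <- nrow(data)
  if (method %in% c("knn", "pcc")) {
    sds <- apply(data, 1L, stats::sd)
    if (any(sds < 1e-12))
      warnf("constant channel: correlations with it defined as 0")
    A <- abs(suppressWarnings(stats::cor(t(data))))
    A[!is.finite(A)] <- 0
    if (method == "pcc") { diag(A) <- 1; return(A) }
    if (k >= N) stopf("knn requires k < N (k = %d, N = %d)", k, N)
    diag(A) <- -Inf
    B <- matrix(0, N, N)
    for (m in seq_len(N)) B[m, order(A[m, ], decreasing = TRUE)[seq_len(k)]] <- 1
    return(pmax(B, t(B)))
  }
  if (method == "plv") {
    ph <- apply(data, 1L, function(x) Arg(analytic_signal(x)))  # [Ts x N]
    A <- diag(N)
    for (m in seq_len(N - 1L)) for (q in (m + 1L):N) {
      v <- Mod(mean(exp(1i * (ph[, m] - ph[, q]))))
      A[m, q] <- A[q, m] <- v
    }
    return(A)
  }
  # mutual information, equal-width histograms
  Ts <- ncol(data)
  nb <- ceiling(sqrt(Ts))
  disc <- apply(data, 1L, function(x) {
    r <- range(x)
    if (diff(r) < 1e-300) return(rep(1L, length(x)))
    pmin(pmax(findInterval(x, seq(r[1], r[2], length.out = nb + 1L),
                           rightmost.closed = TRUE), 1L), nb)
  })                                                            # [Ts x N]
  M <- matrix(0, N, N)
  for (m in seq_len(N)) for (q in m:N) {
    M[m, q] <- M[q, m] <- hist_mutual_info(disc[, m], disc[, q], nb)
  }
  rng <- range(M)
  if (diff(rng) < 1e-300) return(matrix(0, N, N))
  (M - rng[1]) / diff(rng)
}

# Analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hist_mutual_info <- function(a, b, nb) {
  jt <- table(factor(a, levels = seq_len(nb)), factor(b, levels = seq_len(nb)))
  p <- jt / sum(jt)
  pm <- rowSums(p); pn <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pm, pn)[nz]))
}

#' Export an adjacency matrix as a labelled text table
#'
#' @param A Square adjacency matrix.
#' @param file Output path (tab-separated, channel names as header row and
#'   first column).
#' @param channel_names Optional channel labels (defaults to dimnames).
#' @export
export_adjacency <- function(A, file, channel_names = NULL) {
  nm <- channel_names %||% rownames(A) %||% paste0("ch", seq_len(nrow(A)))
  df <- data.frame(channel = nm, A, check.names = FALSE)
  colnames(df) <- c("channel", nm)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
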