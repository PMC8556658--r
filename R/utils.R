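# Internal numerical helpers shared across modules.

# Row-wise softmax of a matrix, numerically stabilised.
row_softmax <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  E / rowSums(E)
}

# Row-softmax over the first two dims of an [N, N', B] array, rows = dim 1.
row_softmax_arr <- function(A) {
  d <- dim(A)
  # rearrange so each (row, batch) pair is a row of a matrix with d[2] columns
  M <- matrix(aperm(A, c(1L, 3L, 2L)), nrow = d[1] * d[3], ncol = d[2])
  S <- row_softmax(M)
  aperm(array(S, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
}

# Backward pass of row-softmax: given output A (rows sum to 1) and upstream
# gradient dA, return gradient with respect to the logits.
row_softmax_backward <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

row_softmax_backward_arr <- function(A, dA) {
  d <- dim(A)
  s <- apply(A * dA, c(1L, 3L), sum)                      # [N, B]
  sexp <- aperm(array(s, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
  A * (dA - sexp)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Glorot-style uniform initialisation.
glorot <- function(dims) {
  fan <- if (length(dims) >= 2L) dims[1] + dims[2] else dims[1] + 1
  lim <- sqrt(6 / fan)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

small_uniform <- function(dims, eps = 1e-2) {
  array(stats::runif(prod(dims), -eps, eps), dim = dims)
}

# Derive independent sub-seeds from one master seed so that e.g. domain-head
# initialisation and minibatch shuffling consume disjoint RNG streams.
derive_seeds <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  list(shared_init = s[1], domain_init = s[2], shuffle = s[3],
       valsplit = s[4], misc = s[5])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
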