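#' Gradient reversal layer
#'
#' Identity in the forward pass. During backpropagation the upstream
#' gradient is multiplied by `-beta` on its way into the feature
#' extractor, which turns joint minimization of the label and domain
#' cross-entropies into the adversarial saddle objective: the domain head
#' learns to identify the subject while the features are pushed to make
#' that impossible. Within the training engine the reversal is realized by
#' [grl_backward()]; this function documents and implements the forward
#' contract.
#'
#' @param x Any numeric input.
#' @param beta Reversal strength (>= 0).
#' @return `x`, unchanged.
#' @export
gradient_reversal <- function(x, beta = 0.5) {
  if (beta < 0) stopf("beta must be >= 0")
  x
}

#' Backward pass of the gradient reversal layer
#'
#' @param grad Upstream gradient arriving from the domain classifier.
#' @param beta Reversal strength.
#' @return `-beta * grad`, the gradient forwarded into the feature
#'   extractor.
#' @export
grl_backward <- function(grad, beta = 0.5) {
  if (beta < 0) stopf("beta must be >= 0")
  -beta * grad
}

#' Label and domain head predictions
#'
#' Affine-softmax readouts over a (flattened) feature vector: the label
#' head predicts the sleep stage over `R_y` classes, the domain head (one
#' hidden ReLU layer, then affine-softmax) predicts which training subject
#' the window came from over `R_d` domains.
#'
#' @param features Numeric feature vector.
#' @param heads List with `wy [R_y x p]`, `by [R_y]`, and optionally
#'   `wh [h x p]`, `bh [h]`, `wd [R_d x h]`, `bd [R_d]`.
#' @return List with simplex vectors `y_hat` and (when domain parameters
#'   are present) `d_hat`.
#' @export
predict_heads <- function(features, heads) {
  f <- as.numeric(features)
  y_hat <- drop(softmax_vec(heads$wy %*% f + heads$by))
  out <- list(y_hat = y_hat)
  if (!is.null(heads$wd)) {
    h <- relu(drop(heads$wh %*% f + heads$bh))
    out$d_hat <- drop(softmax_vec(heads$wd %*% h + heads$bd))
  }
  out
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Cross-entropy of a predicted class distribution
#'
#' `-log p[true]` for a single prediction, or the mean over a batch when
#' `pred` is a matrix (rows = samples). Probabilities are clamped below at
#' `floor` with a warning, so a confidently wrong prediction yields a
#' large finite loss.
#'
#' @param pred Simplex vector, or matrix `[B x R]` of simplex rows.
#' @param true_index 1-based true class index (vector for batches).
#' @param floor Probability clamp, default 1e-12.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(pred, true_index, floor = 1e-12) {
  if (is.matrix(pred)) {
    p <- pred[cbind(seq_len(nrow(pred)), true_index)]
  } else {
    p <- pred[true_index]
  }
  if (any(p < floor)) {
    warnf("predicted probability below %g clamped", floor)
    p <- pmax(p, floor)
  }
  mean(-log(p))
}

#' Combined training objective
#'
#' `loss_total = loss_y + loss_d + gamma * loss_graph`. Both heads
#' minimize their cross-entropies; the adversarial sign of the domain term
#' is carried by the gradient reversal layer on the path into the feature
#' extractor (strength `beta`), not by the reported scalar. `gamma`
#' weights the graph-learning regularizer.
#'
#' @param loss_y,loss_d,loss_graph Component losses (finite).
#' @param beta Reversal strength (recorded, not applied here).
#' @param gamma Graph-loss weight.
#' @return List of class `sg_loss_report` with components and `loss_total`.
#' @export
total_loss <- function(loss_y, loss_d = 0, loss_graph = 0, beta = 0.5,
                       gamma = 1e-4) {
  stopifnot(is.finite(loss_y), is.finite(loss_d), is.finite(loss_graph))
  structure(list(loss_y = loss_y, loss_d = loss_d, loss_graph = loss_graph,
                 beta = beta, gamma = gamma,
                 loss_total = loss_y + loss_d + gamma * loss_graph),
            class = "sg_loss_report")
}
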