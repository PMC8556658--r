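#' Model configuration
#'
#' Collects every tunable of the two-view network and its training loop,
#' including the component switches that define the ablation ladder (see
#' [sg_variant()]).
#'
#' @param d Temporal context radius; window length is `Tn = 2d + 1`.
#' @param K Chebyshev order (number of polynomials).
#' @param channels Channels per graph-convolution block (`C_l`).
#' @param k_t Temporal convolution kernel length (odd).
#' @param beta Gradient-reversal strength for domain generalization.
#' @param gamma Weight of the graph-learning regularizer in the total loss.
#' @param lambda_reg Frobenius weight inside the graph-learning loss.
#' @param lr,batch_size,epochs Optimizer settings (Adam).
#' @param lr_decay Learning-rate annealing exponent: the rate follows
#'   `lr / (1 + 10 p)^lr_decay` over training progress p (0 disables).
#'   Mild annealing stabilizes the adversarial endgame without freezing
#'   the features before the ramped reversal strength can act.
#' @param val_fraction Fraction of training windows held out for
#'   checkpoint selection and early stopping (0 disables both).
#' @param patience Early-stopping patience in epochs (set to `epochs` to
#'   select the best checkpoint without stopping early).
#' @param select_after With domain generalization active, checkpoints are
#'   only eligible for selection once this fraction of training has
#'   elapsed (default 0.6), i.e. after the reversal ramp: the early
#'   epochs have the best label loss but still carry full subject
#'   information, so selecting among them would undo the adversarial
#'   training.
#' @param average_after Polyak averaging: fraction of training after
#'   which epoch-end parameter snapshots are averaged into the returned
#'   model (NULL disables). Saddle-point iterations converge in their
#'   averaged iterates even when the raw iterates oscillate, so
#'   averaging the post-ramp epochs stabilizes the adversarial endgame.
#' @param head_refit After averaging, refit the label head alone on the
#'   frozen fused features (the feature extractor is untouched, so the
#'   representation -- and any subject information it lacks -- is
#'   unchanged; this just realigns the stage readout with the averaged
#'   extractor). Default TRUE whenever averaging is active.
#' @param domain_hidden Hidden units of the domain classifier.
#' @param domain_steps Extra domain-head-only refit steps per minibatch
#'   (the shared parameters are frozen during these), keeping the
#'   adversary close to its optimum so the reversed gradient points along
#'   genuinely subject-discriminative directions.
#' @param domain_replay Number of recent minibatches of frozen features
#'   kept in a replay buffer for the head refits; refitting on several
#'   hundred samples instead of one batch makes the adversary's estimate
#'   of the subject-discriminative directions far less noisy.
#' @param domain_smooth Label smoothing on the domain targets (keeps the
#'   domain softmax away from saturation so the reversed gradient stays
#'   informative; 0 disables).
#' @param beta_warmup Ramp the reversal strength from 0 to `beta` over
#'   training with the sigmoid schedule `2 / (1 + exp(-10 p)) - 1`
#'   (p = training progress), letting the staging task establish before
#'   adversarial pressure peaks.
#' @param class_weights `"none"` or `"inverse"` (inverse-frequency weights
#'   on the label loss).
#' @param seed Master seed; all run randomness derives from it.
#' @param temporal_conv,attention,fc_view,dc_view,domain_generalization
#'   Component switches.
#' @param n_classes Number of stage classes (5).
#' @return A list of class `sg_config`.
#' @export
sg_config <- function(d = 2L, K = 3L, channels = 10L, k_t = 3L,
                      beta = 0.5, gamma = 1e-4, lambda_reg = 0.001,
                      lr = 1e-3, batch_size = 64L, epochs = 30L,
                      lr_decay = 0,
                      val_fraction = 0, patience = 20L, select_after = 0.6,
                      average_after = NULL, head_refit = !is.null(average_after),
                      domain_hidden = 64L, domain_steps = 2L,
                      domain_replay = 8L, domain_smooth = 0.1,
                      beta_warmup = TRUE,
                      class_weights = c("none", "inverse"),
                      seed = 1L,
                      temporal_conv = TRUE, attention = TRUE,
                      fc_view = TRUE, dc_view = TRUE,
                      domain_generalization = TRUE, n_classes = 5L) {
  class_weights <- match.arg(class_weights)
  if (!fc_view && !dc_view) stopf("at least one view must be enabled")
  if (k_t %% 2L == 0L) stopf("k_t must be odd")
  if (K < 1L) stopf("K must be >= 1")
  if (beta < 0) stopf("beta must be >= 0")
  if (lambda_reg < 0) stopf("lambda_reg must be >= 0")
  structure(list(d = as.integer(d), K = as.integer(K),
                 channels = as.integer(channels), k_t = as.integer(k_t),
                 beta = beta, gamma = gamma, lambda_reg = lambda_reg,
                 lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 patience = as.integer(patience), select_after = select_after,
                 average_after = average_after,
                 head_refit = isTRUE(head_refit),
                 domain_hidden = as.integer(domain_hidden),
                 domain_steps = as.integer(domain_steps),
                 domain_replay = as.integer(domain_replay),
                 domain_smooth = domain_smooth,
                 beta_warmup = isTRUE(beta_warmup),
                 class_weights = class_weights, seed = as.integer(seed),
                 n_classes = as.integer(n_classes),
                 enabled = list(temporal_conv = temporal_conv,
                                attention = attention,
                                fc_view = fc_view, dc_view = dc_view,
                                domain_generalization = domain_generalization)),
            class = "sg_config")
}

#' Ablation-ladder configurations
#'
#' The five stacked variants used to assess each component:
#' \describe{
#'   \item{a}{spatial graph convolution on the distance graph only.}
#'   \item{b}{a: plus temporal convolution.}
#'   \item{c}{b: plus spatial and temporal attention.}
#'   \item{d}{c: plus the learned functional-connectivity view and fusion.}
#'   \item{e}{d: plus adversarial domain generalization (the full model).}
#' }
#'
#' @param variant One of `"a"`..`"e"`.
#' @param ... Further arguments passed to [sg_config()].
#' @return An `sg_config`.
#' @export
sg_variant <- function(variant = c("a", "b", "c", "d", "e"), ...) {
  variant <- match.arg(variant)
  lvl <- match(variant, c("a", "b", "c", "d", "e"))
  sg_config(temporal_conv = lvl >= 2L, attention = lvl >= 3L,
            fc_view = lvl >= 4L, dc_view = TRUE,
            domain_generalization = lvl >= 5L, ...)
}

#' Build an (untrained) model
#'
#' Allocates all parameters for the configured components with
#' seed-deterministic initialization and precomputes the distance-graph
#' Chebyshev basis. Shared (feature/label) parameters and domain-head
#' parameters draw from independent RNG streams derived from the seed, so
#' ablating the domain head does not disturb the rest of the
#' initialization.
#'
#' @param config An [sg_config()].
#' @param montage An [sg_montage()].
#' @param Fd Input features per node.
#' @param n_domains Number of training subjects (required when domain
#'   generalization is enabled; >= 2).
#' @return An object of class `sg_model`.
#' @export
build_model <- function(config, montage, Fd = 6L, n_domains = NULL) {
  stopifnot(inherits(config, "sg_config"), inherits(montage, "sg_montage"))
  N <- length(montage$names)
  Tn <- 2L * config$d + 1L
  seeds <- derive_seeds(config$seed)
  params <- with_seed(seeds$shared_init,
                      init_shared_params(N, Fd, Tn, config, config$n_classes))
  if (config$enabled$domain_generalization) {
    if (is.null(n_domains) || n_domains < 2L)
      stopf("domain generalization requires n_domains >= 2 training subjects")
    params <- c(params, with_seed(seeds$domain_init,
                                  init_domain_params(N, Tn, config, n_domains)))
  }
  A_dc <- build_distance_adjacency(montage)
  Lt_dc <- scaled_laplacian(A_dc)
  cb <- cheb_polynomials(Lt_dc, config$K)
  structure(list(params = params, config = config, montage = montage,
                 Fd = as.integer(Fd), Tn = Tn, N = N,
                 n_domains = n_domains, domain_levels = NULL,
                 A_dc = A_dc,
                 fixed_cheb = list(basis = cb, stack = do.call(rbind, cb)),
                 history = NULL, trained = FALSE),
            class = "sg_model")
}

#' @export
print.sg_model <- function(x, ...) {
  en <- x$config$enabled
  cat(sprintf(
    "<sg_model> N=%d channels, Fd=%d, Tn=%d | views:%s%s attention:%s tconv:%s DG:%s | %s\n",
    x$N, x$Fd, x$Tn,
    if (en$fc_view) " FC" else "", if (en$dc_view) " DC" else "",
    en$attention, en$temporal_conv, en$domain_generalization,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of learnable parameters
#' @param model An `sg_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, 0L))
}

# Precompute |x_m - x_n| center-epoch pair tensors for all windows.
precompute_pairdiff <- function(windows) {
  d <- dim(windows$x)
  N <- d[1]; F <- d[2]; Tn <- d[3]; W <- d[4]
  tc <- (Tn + 1L) %/% 2L
  Xc <- windows$x[, , tc, , drop = FALSE]   # [N F 1 W]
  dim(Xc) <- c(N, F, W)
  PD <- abs(array(Xc[rep(seq_len(N), times = N), , ], c(N, N, F, W)) -
              aperm(array(Xc[rep(seq_len(N), times = N), , ], c(N, N, F, W)),
                    c(2L, 1L, 3L, 4L)))
  P2 <- aperm(PD^2, c(3L, 1L, 2L, 4L))
  D2 <- array(colSums(matrix(P2, F, N * N * W)), c(N, N, W))
  list(PD = PD, D2 = D2)
}

#' Train a model
#'
#' Minimizes `loss_y + loss_d + gamma * loss_graph` by minibatch Adam.
#' Both cross-entropies are minimized directly; the adversarial coupling
#' of the domain term enters through the gradient reversal layer, which
#' scales the domain gradient by `-beta` on its way into the shared
#' feature extractor. With `beta = 0` the domain head becomes an
#' independently trained probe whose gradients never touch the shared
#' parameters, so the label-prediction trajectory is bit-identical to a
#' run without domain generalization.
#'
#' @param model An untrained [build_model()] output.
#' @param windows Standardized training `sg_windows` (use
#'   [standardize_features()] on training subjects only).
#' @param verbose Print per-epoch losses.
#' @return The trained `sg_model` with a `history` data frame
#'   (per-epoch `loss_y`, `loss_d`, `loss_graph`, and validation loss when
#'   early stopping is active).
#' @export
sg_train <- function(model, windows, verbose = FALSE) {
  config <- model$config
  W <- dim(windows$x)[4]
  subj <- unique(windows$subject)
  if (config$enabled$domain_generalization) {
    if (length(subj) < 2L)
      stopf("domain generalization requires >= 2 training subjects (R_d >= 2); got %d",
            length(subj))
    if (is.null(model$n_domains)) stopf("model built without n_domains")
    if (length(subj) != model$n_domains)
      stopf("model expects %d domains but windows contain %d subjects",
            model$n_domains, length(subj))
  }
  model$domain_levels <- sort(subj)
  dom <- match(windows$subject, model$domain_levels)
  y <- windows$y + 1L
  pc <- if (config$enabled$fc_view) precompute_pairdiff(windows) else NULL
  class_wt <- NULL
  if (config$class_weights == "inverse") {
    tab <- tabulate(y, nbins = config$n_classes)
    class_wt <- sum(tab) / (config$n_classes * pmax(tab, 1))
  }
  seeds <- derive_seeds(config$seed)
  # optional validation split for early stopping
  use_val <- config$val_fraction > 0
  if (use_val) {
    n_val <- max(1L, round(config$val_fraction * W))
    val_idx <- with_seed(seeds$valsplit, sample.int(W, n_val))
    tr_idx <- setdiff(seq_len(W), val_idx)
  } else {
    tr_idx <- seq_len(W)
    val_idx <- integer(0)
  }
  state <- adam_init(model$params)
  replay_f <- NULL; replay_d <- NULL          # adversary replay buffer
  avg <- NULL; n_avg <- 0L                    # Polyak iterate average
  hist <- list()
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    # beta warm-up: sigmoid ramp of the reversal strength over training
    prog <- ep / config$epochs
    if (isTRUE(config$beta_warmup) && config$beta > 0)
      config$beta <- model$config$beta * (2 / (1 + exp(-10 * prog)) - 1)
    lr_ep <- config$lr / (1 + 10 * prog)^config$lr_decay
    ord <- with_seed(seeds$shuffle %% 2000000000L + ep,
                     sample(tr_idx, length(tr_idx)))
    nb <- ceiling(length(ord) / config$batch_size)
    ep_ly <- ep_ld <- ep_lg <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1L) * config$batch_size + 1L):
                   min(ib * config$batch_size, length(ord))]
      Xb <- windows$x[, , , idx, drop = FALSE]
      PDb <- if (!is.null(pc)) pc$PD[, , , idx, drop = FALSE]
      D2b <- if (!is.null(pc)) pc$D2[, , idx, drop = FALSE]
      fwd <- model_fwd(model$params, Xb, config, model$fixed_cheb,
                       PDb = PDb, D2b = D2b)
      db <- if (config$enabled$domain_generalization) dom[idx]
      ls <- batch_losses(fwd, y[idx], db, class_wt,
                         config$domain_smooth %||% 0)
      grads <- model_bwd(model$params, Xb, config, fwd, y[idx], db,
                         class_wt, D2b)
      st <- adam_step(model$params, grads, state, lr = lr_ep)
      model$params <- st$params
      state <- st$state
      # adversary refits on a replay buffer of recent frozen features:
      # only worthwhile once the reversal has strength
      if (!is.null(db) && (config$domain_steps %||% 0L) > 0L &&
          config$beta >= 0.05 * model$config$beta) {
        keep <- (config$domain_replay %||% 8L) * config$batch_size
        replay_f <- cbind(fwd$f, replay_f)
        replay_d <- c(db, replay_d)
        if (length(replay_d) > keep) {
          replay_f <- replay_f[, seq_len(keep), drop = FALSE]
          replay_d <- replay_d[seq_len(keep)]
        }
        for (k in seq_len(config$domain_steps)) {
          hg <- domain_head_grads(model$params, replay_f, replay_d, config)
          upd <- adam_step_keys(model$params, hg, state, lr = lr_ep,
                                keys = c("wh", "bh", "wd", "bd"))
          model$params <- upd$params
          state <- upd$state
        }
      }
      ep_ly <- ep_ly + ls$loss_y * length(idx)
      ep_ld <- ep_ld + ls$loss_d * length(idx)
      ep_lg <- ep_lg + ls$loss_graph * length(idx)
    }
    rec <- list(epoch = ep, loss_y = ep_ly / length(ord),
                loss_d = ep_ld / length(ord), loss_graph = ep_lg / length(ord),
                val_loss_y = NA_real_)
    if (use_val) {
      vfwd <- forward_in_chunks(model, subset_windows(windows, val_idx))
      pv <- vfwd$yhat[cbind(y[val_idx], seq_along(val_idx))]
      rec$val_loss_y <- mean(-log(pmax(pv, 1e-12)))
      adversarial <- config$enabled$domain_generalization &&
        model$config$beta > 0 && isTRUE(config$beta_warmup)
      eligible <- !adversarial || prog >= (config$select_after %||% 0)
      if (eligible && rec$val_loss_y < best$loss - 1e-6) {
        best <- list(loss = rec$val_loss_y, params = model$params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    if (!is.null(config$average_after) && prog >= config$average_after) {
      fp <- flatten_params(model$params)
      avg <- if (is.null(avg)) fp else Map(`+`, avg, fp)
      n_avg <- n_avg + 1L
    }
    hist[[ep]] <- rec
    if (is.function(config$trace_fn)) config$trace_fn(model, ep)
    if (verbose)
      message(sprintf("epoch %3d  loss_y %.4f  loss_d %.4f  loss_graph %.4f%s",
                      ep, rec$loss_y, rec$loss_d, rec$loss_graph,
                      if (use_val) sprintf("  val %.4f", rec$val_loss_y) else ""))
    if (use_val && wait >= config$patience) break
  }
  if (n_avg > 0L) {
    for (key in names(avg))
      model$params <- assign_path(model$params,
                                  strsplit(key, "$", fixed = TRUE)[[1]],
                                  avg[[key]] / n_avg)
    if (isTRUE(config$head_refit)) {
      model$trained <- TRUE
      model <- refit_label_head(model, windows, y, class_wt,
                                seed = seeds$misc)
    }
  } else if (use_val && is.finite(best$loss)) {
    model$params <- best$params
  }
  model$history <- do.call(rbind, lapply(hist, as.data.frame))
  model$trained <- TRUE
  model
}

# Refit the affine label head on frozen fused features (softmax
# regression warm-started from the current head). The extractor is not
# touched.
refit_label_head <- function(model, windows, y, class_wt, seed,
                             epochs = 30L) {
  fwd <- forward_in_chunks(model, windows)
  f <- fwd$f
  W <- ncol(f)
  pars <- list(wy = model$params$wy, by = model$params$by)
  state <- adam_init(pars)
  bs <- model$config$batch_size
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed %% 2000000000L + ep, sample.int(W))
    nb <- ceiling(W / bs)
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1L) * bs + 1L):min(ib * bs, W)]
      fb <- f[, idx, drop = FALSE]
      ph <- t(row_softmax(t(pars$wy %*% fb + pars$by)))
      dl <- ph
      ii <- cbind(y[idx], seq_along(idx))
      dl[ii] <- dl[ii] - 1
      if (!is.null(class_wt)) {
        wts <- class_wt[y[idx]]
        dl <- sweep(dl, 2L, wts, `*`) / sum(wts)
      } else dl <- dl / length(idx)
      st <- adam_step(pars, list(wy = tcrossprod(dl, fb), by = rowSums(dl)),
                      state, lr = model$config$lr)
      pars <- st$params
      state <- st$state
    }
  }
  model$params$wy <- pars$wy
  model$params$by <- pars$by
  model
}

# Forward a full window set in batches, concatenating the head outputs.
forward_in_chunks <- function(model, windows, keep_maps = FALSE) {
  config <- model$config
  W <- dim(windows$x)[4]
  pc <- if (config$enabled$fc_view) precompute_pairdiff(windows) else NULL
  bs <- config$batch_size
  nb <- ceiling(W / bs)
  yhat <- NULL; dhat <- NULL; fmat <- NULL
  A_fc <- if (keep_maps && config$enabled$fc_view)
    array(0, c(model$N, model$N, W))
  Pp <- if (keep_maps && config$enabled$attention)
    array(0, c(model$N, model$N, W))
  Qp <- if (keep_maps && config$enabled$attention)
    array(0, c(model$Tn, model$Tn, W))
  for (ib in seq_len(nb)) {
    idx <- ((ib - 1L) * bs + 1L):min(ib * bs, W)
    Xb <- windows$x[, , , idx, drop = FALSE]
    fwd <- model_fwd(model$params, Xb, config, model$fixed_cheb,
                     PDb = if (!is.null(pc)) pc$PD[, , , idx, drop = FALSE],
                     D2b = if (!is.null(pc)) pc$D2[, , idx, drop = FALSE])
    yhat <- cbind(yhat, fwd$yhat)
    if (!is.null(fwd$dhat)) dhat <- cbind(dhat, fwd$dhat)
    fmat <- cbind(fmat, fwd$f)
    if (keep_maps) {
      vc <- fwd$caches$fc %||% fwd$caches$dc
      if (!is.null(A_fc)) A_fc[, , idx] <- fwd$A_fc
      if (!is.null(Pp)) Pp[, , idx] <- vc$Pp
      if (!is.null(Qp)) Qp[, , idx] <- vc$ta$Qp
    }
  }
  list(yhat = yhat, dhat = dhat, f = fmat, A_fc = A_fc, Pp = Pp, Qp = Qp)
}

#' Predict sleep stages for a set of windows
#'
#' Deterministic forward pass; the predicted stage is the argmax of the
#' label-head probabilities with ties broken toward the lower class index.
#'
#' @param object A trained `sg_model`.
#' @param windows Standardized `sg_windows` (same montage/standardizer as
#'   training).
#' @param keep_maps Also return per-window learned adjacencies and
#'   attention maps (for the interpretability exports).
#' @param ... Unused.
#' @return List with `labels` (0-4), `prob` `[W x 5]`, `features`
#'   (flattened fused features `[p x W]`), and when `keep_maps = TRUE`
#'   `A_fc`, `P_prime`, `Q_prime` arrays.
#' @export
predict.sg_model <- function(object, windows, keep_maps = FALSE, ...) {
  if (dim(windows$x)[1] != object$N)
    stopf("windows have %d channels but model expects %d",
          dim(windows$x)[1], object$N)
  if (dim(windows$x)[3] != object$Tn)
    stopf("windows have Tn=%d but model expects Tn=%d",
          dim(windows$x)[3], object$Tn)
  fwd <- forward_in_chunks(object, windows, keep_maps = keep_maps)
  labels <- apply(fwd$yhat, 2L, which.max) - 1L   # first max = lower index
  out <- list(labels = labels, prob = t(fwd$yhat), features = fwd$f)
  if (keep_maps) {
    out$A_fc <- fwd$A_fc
    out$P_prime <- fwd$Pp
    out$Q_prime <- fwd$Qp
  }
  out
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive holding all parameters, the
#' configuration snapshot and the montage; reloading reproduces
#' predictions bit-exactly.
#'
#' @param model An `sg_model`.
#' @param path File path.
#' @return `path` (save) or the restored `sg_model` (load).
#' @export
sg_save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname sg_save_model
#' @export
sg_load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sg_model"))
  m
}

#' Reference configuration for the synthetic benchmark
#'
#' The model/training configuration used by the package's standard
#' synthetic-cohort experiment (leave-one-subject-out staging plus
#' subject-invariance probes on the default [sg_synth_spec()] cohort):
#' a compact two-view model (4 channels per block, 32 domain-hidden
#' units) trained for 100 epochs with reversal strength 2, two
#' replay-buffer adversary refits per batch, and no learning-rate decay.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [sg_config()].
#' @return An `sg_config`.
#' @export
sg_reference_config <- function(seed = 1L, ...) {
  defaults <- list(d = 2L, K = 3L, channels = 4L, k_t = 3L,
                   beta = 1.2, domain_hidden = 32L, domain_steps = 2L,
                   domain_replay = 8L, domain_smooth = 0.1,
                   epochs = 100L, batch_size = 64L, lr = 1e-3, lr_decay = 0,
                   average_after = 0.6, seed = seed)
  do.call(sg_config, utils::modifyList(defaults, list(...)))
}
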