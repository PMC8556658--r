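#' Confusion matrix
#'
#' @param true,pred Integer stage labels (0-based), equal length.
#' @param n_classes Number of classes (default 5).
#' @return Integer matrix `[R x R]`, rows = true, cols = predicted, with
#'   stage names on both margins; class `sg_confusion`.
#' @export
confusion_matrix <- function(true, pred, n_classes = 5L) {
  stopifnot(length(true) == length(pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  nm <- stage_names(n_classes)
  dimnames(cm) <- list(true = nm, predicted = nm)
  structure(cm, class = c("sg_confusion", "matrix", "array"))
}

stage_names <- function(n = 5L) {
  if (n == 5L) c("Wake", "N1", "N2", "N3", "REM") else paste0("class", 0:(n - 1L))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. Per-class F1 is `2PR / (P + R)` with 0 for
#' degenerate classes; macro-F1 averages F1 over the classes present in
#' the truth. Cohen's kappa is `(p_o - p_e) / (1 - p_e)` with the chance
#' agreement `p_e` from marginal products; the degenerate single-cell case
#' (`p_e = 1`) is defined as 1 when observed agreement is perfect and 0
#' otherwise, with a warning.
#'
#' @param cm A square count matrix (rows = true, cols = predicted).
#' @return List with `accuracy`, `macro_f1`, `per_class_f1`, `kappa`.
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stopf("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  R <- nrow(cm)
  f1 <- numeric(R)
  for (r in seq_len(R)) {
    tp <- cm[r, r]
    prec_den <- sum(cm[, r]); rec_den <- sum(cm[r, ])
    if (tp == 0) { f1[r] <- 0; next }
    P <- tp / prec_den; Rc <- tp / rec_den
    f1[r] <- 2 * P * Rc / (P + Rc)
  }
  names(f1) <- rownames(cm) %||% stage_names(R)
  present <- rowSums(cm) > 0
  macro <- mean(f1[present])
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1 - 1e-12) {
    warnf("degenerate chance agreement p_e = 1; kappa defined as %d",
          as.integer(acc >= 1 - 1e-12))
    kap <- if (acc >= 1 - 1e-12) 1 else 0
  } else {
    kap <- (acc - pe) / (1 - pe)
  }
  list(accuracy = acc, macro_f1 = macro, per_class_f1 = f1, kappa = kap)
}

#' Subject-independent fold plan
#'
#' Subjects (never individual windows) are shuffled with the seed and
#' dealt round-robin into folds, so every subject sits in exactly one fold
#' and no recording is split across train and test. Fold sizes differ by
#' at most one subject.
#'
#' @param subject_ids Character vector of subject identifiers (one per
#'   subject; duplicates are collapsed).
#' @param n_folds Number of folds (<= number of subjects).
#' @param seed Shuffle seed.
#' @return List of class `sg_fold_plan`: `assignments` (named fold index
#'   per subject) and `n_folds`.
#' @export
subject_kfold <- function(subject_ids, n_folds, seed = 1L) {
  subs <- unique(as.character(subject_ids))
  n_folds <- as.integer(n_folds)
  if (n_folds > length(subs))
    stopf("n_folds = %d exceeds the %d available subjects", n_folds, length(subs))
  ord <- with_seed(seed, sample(subs))
  asg <- stats::setNames(rep(seq_len(n_folds), length.out = length(ord)), ord)
  structure(list(assignments = asg, n_folds = n_folds), class = "sg_fold_plan")
}

#' Subject-independent cross-validation
#'
#' For each fold: feature standardization statistics are computed on the
#' training subjects only, a model is built and trained on them, and the
#' held-out subjects are evaluated with the training-set transform. No
#' test-subject window ever influences standardization or parameters.
#'
#' @param cohort List of per-subject window sets (`sg_windows`, one per
#'   subject, unstandardized) such as [windows_from_cohort()] returns.
#' @param config An [sg_config()].
#' @param montage The shared [sg_montage()].
#' @param n_folds Number of folds; defaults to leave-one-subject-out.
#' @param seed Fold-shuffle seed (training seeds derive from
#'   `config$seed + fold`).
#' @param verbose Print per-fold progress.
#' @param keep_models Also return the per-fold trained models (with their
#'   fold's standardization statistics attached).
#' @return List of class `sg_cv_report`: `fold_metrics` (per fold),
#'   `pooled` metrics over the concatenated predictions, `pooled_cm`,
#'   `fold_cms`, `plan`, and `predictions` (per-window data frame).
#' @export
cross_validate <- function(cohort, config, montage, n_folds = length(cohort),
                           seed = 1L, verbose = FALSE, keep_models = FALSE) {
  subs <- vapply(cohort, function(w) w$subject[1], "")
  names(cohort) <- subs
  plan <- subject_kfold(subs, n_folds, seed)
  fold_cms <- vector("list", plan$n_folds)
  models <- vector("list", plan$n_folds)
  fold_metrics <- vector("list", plan$n_folds)
  preds <- list()
  for (fold in seq_len(plan$n_folds)) {
    test_subs <- names(plan$assignments)[plan$assignments == fold]
    train_subs <- setdiff(subs, test_subs)
    tr <- bind_windows(cohort[train_subs])
    te <- bind_windows(cohort[test_subs])
    miss <- setdiff(0:(config$n_classes - 1L), unique(tr$y))
    if (length(miss))
      warnf("fold %d: classes %s absent from training windows", fold,
            paste(miss, collapse = ","))
    stats <- compute_feature_stats(tr)
    tr <- standardize_features(tr, stats)
    te <- standardize_features(te, stats)
    cfg <- config
    cfg$seed <- config$seed + fold
    model <- build_model(cfg, montage, Fd = dim(tr$x)[2],
                         n_domains = if (cfg$enabled$domain_generalization)
                           length(train_subs))
    model <- sg_train(model, tr)
    attr(model, "feature_stats") <- stats
    if (keep_models) models[[fold]] <- model
    pr <- predict(model, te)
    cm <- confusion_matrix(te$y, pr$labels, config$n_classes)
    fold_cms[[fold]] <- cm
    fold_metrics[[fold]] <- compute_metrics(cm)
    preds[[fold]] <- data.frame(subject = te$subject, center = te$center,
                                true = te$y, pred = pr$labels, fold = fold)
    if (verbose)
      message(sprintf("fold %d/%d  held-out {%s}  acc %.3f", fold,
                      plan$n_folds, paste(test_subs, collapse = ","),
                      fold_metrics[[fold]]$accuracy))
  }
  pooled_cm <- Reduce(`+`, lapply(fold_cms, unclass))
  dimnames(pooled_cm) <- dimnames(fold_cms[[1]])
  structure(list(fold_metrics = fold_metrics,
                 fold_cms = fold_cms,
                 pooled_cm = pooled_cm,
                 pooled = compute_metrics(pooled_cm),
                 plan = plan,
                 models = if (keep_models) models,
                 predictions = do.call(rbind, preds)),
            class = "sg_cv_report")
}

#' @export
print.sg_cv_report <- function(x, ...) {
  accs <- vapply(x$fold_metrics, `[[`, 0, "accuracy")
  cat(sprintf("<sg_cv_report> %d folds | pooled acc %.3f  macro-F1 %.3f  kappa %.3f | fold acc %.3f +- %.3f\n",
              x$plan$n_folds, x$pooled$accuracy, x$pooled$macro_f1,
              x$pooled$kappa, mean(accs), stats::sd(accs)))
  invisible(x)
}

#' Train a subject-identification probe on frozen features
#'
#' Fits a softmax (multinomial logistic) readout on fixed feature vectors
#' to measure how much subject identity is still linearly decodable from
#' a representation. Used to verify that domain generalization removes
#' subject information: near-chance probe accuracy means subject-invariant
#' features.
#'
#' @param features Matrix `[p x n]` of frozen feature columns.
#' @param labels Factor-like vector of length n (e.g. subject ids).
#' @param train_frac Fraction of samples used to fit (the rest are the
#'   evaluation set).
#' @param epochs,lr,batch_size Optimizer settings.
#' @param seed Seed for the split, init and batching.
#' @return List with `accuracy` (held-out), `chance` (1 / number of
#'   levels), `levels`.
#' @export
domain_probe <- function(features, labels, train_frac = 0.8, epochs = 60L,
                         lr = 1e-2, batch_size = 128L, seed = 1L) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  yy <- match(labels, lev)
  n <- ncol(features)
  R <- length(lev)
  tr <- with_seed(seed, sample.int(n, round(train_frac * n)))
  te <- setdiff(seq_len(n), tr)
  Wm <- with_seed(seed + 1L, glorot(c(R, nrow(features))))
  bv <- numeric(R)
  state <- adam_init(list(W = Wm, b = bv))
  pars <- list(W = Wm, b = bv)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 10L + ep, sample(tr, length(tr)))
    nb <- ceiling(length(ord) / batch_size)
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1L) * batch_size + 1L):min(ib * batch_size, length(ord))]
      fb <- features[, idx, drop = FALSE]
      logits <- pars$W %*% fb + pars$b
      ph <- apply(logits, 2L, softmax_vec)
      dl <- ph
      ii <- cbind(yy[idx], seq_along(idx))
      dl[ii] <- dl[ii] - 1
      dl <- dl / length(idx)
      st <- adam_step(pars, list(W = dl %*% t(fb), b = rowSums(dl)),
                      state, lr = lr)
      pars <- st$params
      state <- st$state
    }
  }
  logits <- pars$W %*% features[, te, drop = FALSE] + pars$b
  pred <- apply(logits, 2L, which.max)
  list(accuracy = mean(pred == yy[te]), chance = 1 / R, levels = lev)
}
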