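#' Per-stage attention and adjacency summaries
#'
#' Averages the interpretability maps of correctly classified windows per
#' predicted stage: the learned functional-connectivity adjacency
#' (`N x N` per stage), the spatial channel attention (column sums of
#' `P'`, i.e. how much each channel contributes to everyone's update) and
#' the temporal attention profile (the center row of `Q'`, i.e. how the
#' classified epoch weights its context). Deterministic given a fixed
#' model and window set.
#'
#' @param model A trained `sg_model` (attention enabled for the attention
#'   summaries).
#' @param windows Standardized `sg_windows`.
#' @return List of class `sg_attention_summary`: `adjacency` (list of
#'   `N x N` per stage, when the FC view is enabled), `channel_attention`
#'   (`N x stages` matrix), `temporal_attention` (`Tn x stages`),
#'   `n_windows` per stage.
#' @export
summarize_attention <- function(model, windows) {
  pr <- predict(model, windows, keep_maps = TRUE)
  ok <- pr$labels == windows$y
  stages <- stage_names(model$config$n_classes)
  R <- length(stages)
  chan <- matrix(NA_real_, model$N, R, dimnames = list(model$montage$names, stages))
  temp <- matrix(NA_real_, model$Tn, R,
                 dimnames = list(paste0("t", seq_len(model$Tn) - (model$Tn + 1L) %/% 2L),
                                 stages))
  adj <- if (!is.null(pr$A_fc)) stats::setNames(vector("list", R), stages)
  nw <- integer(R)
  tc <- (model$Tn + 1L) %/% 2L
  for (r in seq_len(R)) {
    sel <- which(ok & windows$y == r - 1L)
    nw[r] <- length(sel)
    if (!length(sel)) next
    if (!is.null(pr$P_prime))
      chan[, r] <- rowMeans(apply(pr$P_prime[, , sel, drop = FALSE], 3L, colSums))
    if (!is.null(pr$Q_prime))
      temp[, r] <- rowMeans(matrix(pr$Q_prime[tc, , sel], model$Tn, length(sel)))
    if (!is.null(adj)) {
      adj[[r]] <- apply(pr$A_fc[, , sel, drop = FALSE], c(1L, 2L), mean)
      dimnames(adj[[r]]) <- list(model$montage$names, model$montage$names)
    }
  }
  structure(list(adjacency = adj, channel_attention = chan,
                 temporal_attention = temp, n_windows = nw),
            class = "sg_attention_summary")
}

#' Write attention summaries as delimited text
#'
#' Writes `channel_attention.tsv` (channels x stages) and
#' `temporal_attention.tsv` (context offsets x stages) into `dir`.
#'
#' @param summary An [summarize_attention()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_attention <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ca <- data.frame(channel = rownames(summary$channel_attention),
                   summary$channel_attention, check.names = FALSE)
  utils::write.table(ca, file.path(dir, "channel_attention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ta <- data.frame(offset = rownames(summary$temporal_attention),
                   summary$temporal_attention, check.names = FALSE)
  utils::write.table(ta, file.path(dir, "temporal_attention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write per-stage averaged adjacency tables
#'
#' One tab-separated `adjacency_<stage>.tsv` per stage with channel-name
#' headers.
#'
#' @param summary An [summarize_attention()] result with adjacencies.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_graphs <- function(summary, dir) {
  if (is.null(summary$adjacency))
    stopf("no learned adjacencies in summary (FC view disabled?)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(summary$adjacency)) {
    A <- summary$adjacency[[nm]]
    if (is.null(A)) next
    export_adjacency(A, file.path(dir, sprintf("adjacency_%s.tsv", nm)))
  }
  invisible(dir)
}

#' Write a cross-validation report as text
#'
#' Writes `metrics.tsv` (per-fold and pooled rows), `confusion.tsv`
#' (pooled counts with stage headers) and `summary.json`.
#'
#' @param report An `sg_cv_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(report$fold_metrics), function(i) {
    m <- report$fold_metrics[[i]]
    data.frame(fold = as.character(i), accuracy = m$accuracy,
               macro_f1 = m$macro_f1, kappa = m$kappa)
  })
  rows[[length(rows) + 1L]] <- data.frame(fold = "pooled",
                                          accuracy = report$pooled$accuracy,
                                          macro_f1 = report$pooled$macro_f1,
                                          kappa = report$pooled$kappa)
  utils::write.table(do.call(rbind, rows), file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- as.data.frame.matrix(report$pooled_cm)
  cm <- cbind(true = rownames(cm), cm)
  utils::write.table(cm, file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fold_acc <- vapply(report$fold_metrics, `[[`, 0, "accuracy")
  jsonlite::write_json(
    list(pooled = report$pooled[c("accuracy", "macro_f1", "kappa")],
         fold_accuracy_mean = mean(fold_acc),
         fold_accuracy_sd = stats::sd(fold_acc)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
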