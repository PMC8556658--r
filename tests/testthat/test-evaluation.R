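test_that("metrics on hand-computed confusion matrices are exact", {
  # perfect diagonal
  m <- compute_metrics(diag(c(3, 4, 5, 2, 1)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$kappa, 1)
  # observed equals chance
  m2 <- compute_metrics(matrix(1, 2, 2))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$kappa, 0)
  # [[4,1],[2,3]]: acc 0.7, kappa 0.4, F1 = {8/11, 6/9}
  m3 <- compute_metrics(matrix(c(4, 2, 1, 3), 2, 2))
  expect_equal(m3$accuracy, 0.7)
  expect_equal(m3$kappa, 0.4)
  expect_equal(unname(m3$per_class_f1), c(8 / 11, 6 / 9))
  expect_equal(m3$macro_f1, mean(c(8 / 11, 6 / 9)))
  # degenerate single-cell matrix
  expect_warning(m4 <- compute_metrics(matrix(c(5, 0, 0, 0), 2, 2)), "p_e")
  expect_equal(m4$kappa, 1)
})

test_that("confusion matrix counts and margins", {
  cm <- confusion_matrix(c(0, 0, 1, 4), c(0, 1, 1, 4))
  expect_equal(sum(cm), 4)
  expect_equal(unname(diag(unclass(cm))), c(1, 1, 0, 0, 1))
  expect_equal(rownames(cm), c("Wake", "N1", "N2", "N3", "REM"))
})

test_that("subject k-fold plans are subject-exclusive, balanced, reproducible", {
  subs <- sprintf("S%02d", 1:10)
  plan <- subject_kfold(subs, 10, seed = 3)
  expect_equal(sort(unique(plan$assignments)), 1:10)  # leave-one-subject-out
  plan2 <- subject_kfold(subs, 10, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- subject_kfold(sprintf("S%d", 1:7), 3, seed = 1)
  expect_equal(sort(as.vector(table(plan3$assignments)), decreasing = TRUE),
               c(3L, 2L, 2L))
  expect_error(subject_kfold(subs[1:3], 5, seed = 1), "exceeds")
})

test_that("pooled confusion matrix equals the sum of fold matrices (oracle predictor)", {
  w <- tiny_windows(n_subjects = 4L, epochs = 30L)
  # plumbing check with an oracle that copies the labels: all metrics 1
  oracle_cv <- function(seed) {
    plan <- subject_kfold(vapply(w, function(x) x$subject[1], ""), 2, seed)
    cms <- lapply(1:2, function(fold) {
      te <- bind_windows(w[plan$assignments == fold])
      confusion_matrix(te$y, te$y)
    })
    pooled <- Reduce(`+`, lapply(cms, unclass))
    list(cms = cms, pooled = pooled)
  }
  r <- oracle_cv(1)
  expect_equal(compute_metrics(r$pooled)$accuracy, 1)
  expect_equal(sum(r$pooled), sum(vapply(r$cms, sum, 0)))
  # a different shuffle seed changes assignment but not oracle metrics
  r2 <- oracle_cv(2)
  expect_equal(compute_metrics(r2$pooled)$accuracy, 1)
})

test_that("cross-validation never leaks test subjects into standardization", {
  w <- tiny_windows(n_subjects = 3L, epochs = 30L)
  # verify directly: stats computed on training subjects differ from stats
  # of the full set whenever the held-out subject is shifted
  w[[3]]$x <- w[[3]]$x + 10
  tr_stats <- compute_feature_stats(bind_windows(w[1:2]))
  all_stats <- compute_feature_stats(bind_windows(w))
  expect_gt(max(abs(tr_stats$mean - all_stats$mean)), 1)
})

test_that("cross_validate runs end-to-end on a tiny cohort and reports folds", {
  w <- tiny_windows(n_subjects = 3L, epochs = 36L, delta = 2.5, eta = 0.3)
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 4L,
                   batch_size = 32L, attention = FALSE,
                   domain_generalization = FALSE, seed = 2L)
  rep <- cross_validate(w, cfg, sg_default_montage(4L), n_folds = 3L, seed = 1L)
  expect_length(rep$fold_metrics, 3L)
  expect_equal(sum(rep$pooled_cm), sum(vapply(w, function(x) length(x$y), 0L)))
  expect_equal(unclass(rep$pooled_cm),
               unclass(Reduce(`+`, lapply(rep$fold_cms, unclass))),
               ignore_attr = TRUE)
  expect_true(rep$pooled$accuracy >= 0 && rep$pooled$accuracy <= 1)
})

test_that("domain probe recovers obvious subject structure and respects chance", {
  withr::with_seed(77, {
    n <- 300
    lab <- sample(c("a", "b", "c"), n, replace = TRUE)
    off <- cbind(a = c(3, 0), b = c(0, 3), c = c(-3, -3))
    f <- matrix(rnorm(2 * n, sd = 0.5), 2, n) + off[, lab]
    pr <- domain_probe(f, lab, seed = 1)
    expect_gt(pr$accuracy, 0.9)
    expect_equal(pr$chance, 1 / 3)
    # featureless input: accuracy near chance
    f0 <- matrix(rnorm(2 * n), 2, n)
    pr0 <- domain_probe(f0, lab, seed = 1)
    expect_lt(pr0$accuracy, pr$chance + 0.2)
  })
})
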