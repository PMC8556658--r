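test_that("the ablation ladder allocates strictly more parameters a -> e", {
  mont <- sg_default_montage(5L)
  counts <- vapply(c("a", "b", "c", "d", "e"), function(v) {
    cfg <- sg_variant(v, d = 1L, channels = 4L, seed = 3L)
    count_params(build_model(cfg, mont, Fd = 4L,
                             n_domains = if (v == "e") 3L))
  }, 0L)
  expect_true(all(diff(counts) > 0))
  # variant a allocates no attention / temporal-conv / FC / domain params
  ma <- build_model(sg_variant("a", d = 1L, channels = 4L, seed = 3L),
                    mont, Fd = 4L)
  expect_named(ma$params, c("dc", "wy", "by"))
  expect_named(ma$params$dc, c("Theta", "bg"))
})

test_that("builds with the same seed are identical; different seeds differ", {
  mont <- sg_default_montage(4L)
  cfg <- sg_config(d = 1L, channels = 4L, seed = 5L)
  m1 <- build_model(cfg, mont, Fd = 3L, n_domains = 2L)
  m2 <- build_model(cfg, mont, Fd = 3L, n_domains = 2L)
  expect_identical(m1$params, m2$params)
  cfg2 <- cfg; cfg2$seed <- 6L
  m3 <- build_model(cfg2, mont, Fd = 3L, n_domains = 2L)
  expect_false(identical(m1$params$wy, m3$params$wy))
})

test_that("training converges on linearly separable features with DG off", {
  w <- tiny_windows(n_subjects = 2L, epochs = 60L, delta = 3, eta = 0.2,
                    seed = 71L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 120L,
                   batch_size = 32L, domain_generalization = FALSE,
                   seed = 4L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L)
  m <- sg_train(m, all)
  expect_lt(tail(m$history$loss_y, 1), 0.15)
  expect_true(all(diff(tapply(m$history$loss_y,
                              rep(1:6, each = 20), mean)) < 0))
})

test_that("beta = 0 training yields the identical label trajectory as DG off", {
  w <- tiny_windows(n_subjects = 2L, epochs = 40L, seed = 72L)
  all <- standardize_features(bind_windows(w))
  mont <- sg_default_montage(4L)
  cfg0 <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 5L,
                    batch_size = 32L, beta = 0, seed = 9L)
  m0 <- build_model(cfg0, mont, Fd = 3L, n_domains = 2L)
  m0 <- sg_train(m0, all)
  cfg1 <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 5L,
                    batch_size = 32L, domain_generalization = FALSE, seed = 9L)
  m1 <- build_model(cfg1, mont, Fd = 3L)
  m1 <- sg_train(m1, all)
  expect_identical(m0$params$wy, m1$params$wy)
  expect_identical(m0$params$dc, m1$params$dc)
  expect_identical(m0$history$loss_y, m1$history$loss_y)
})

test_that("prediction is deterministic, tie-broken low, and shape-checked", {
  w <- tiny_windows(seed = 73L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 2L,
                   batch_size = 32L, domain_generalization = FALSE, seed = 1L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L)
  m <- sg_train(m, all)
  p1 <- predict(m, all)
  p2 <- predict(m, all)
  expect_identical(p1, p2)
  expect_true(all(p1$labels %in% 0:4))
  expect_equal(dim(p1$prob), c(dim(all$x)[4], 5L))
  # uniform probabilities break ties toward the lower class index
  expect_equal(which.max(rep(0.2, 5)) - 1L, 0L)
  bad <- all
  bad$x <- bad$x[1:3, , , , drop = FALSE]
  expect_error(predict(m, bad), "channels")
})

test_that("save -> load -> predict is bit-identical", {
  w <- tiny_windows(seed = 74L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 2L,
                   batch_size = 32L, domain_generalization = FALSE, seed = 2L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L)
  m <- sg_train(m, all)
  before <- predict(m, all)
  path <- tempfile(fileext = ".rds")
  sg_save_model(m, path)
  m2 <- sg_load_model(path)
  expect_identical(predict(m2, all), before)
})

test_that("single-subject input with DG enabled is a hard error", {
  w <- tiny_windows(n_subjects = 1L, epochs = 30L, seed = 75L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, channels = 4L, epochs = 1L, seed = 1L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L, n_domains = 2L)
  expect_error(sg_train(m, all), "R_d >= 2")
})

test_that("graph regularizer decreases over training when gamma > 0", {
  w <- tiny_windows(n_subjects = 2L, epochs = 60L, delta = 2, seed = 76L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 12L,
                   batch_size = 32L, gamma = 1e-2,
                   domain_generalization = FALSE, seed = 6L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L)
  m <- sg_train(m, all)
  lg <- m$history$loss_graph
  expect_lt(mean(tail(lg, 3)), mean(head(lg, 3)))
})

test_that("attention summaries are deterministic and exportable", {
  w <- tiny_windows(n_subjects = 2L, epochs = 50L, delta = 2.5, seed = 78L)
  all <- standardize_features(bind_windows(w))
  cfg <- sg_config(d = 1L, K = 2L, channels = 4L, epochs = 6L,
                   batch_size = 32L, domain_generalization = FALSE, seed = 3L)
  m <- build_model(cfg, sg_default_montage(4L), Fd = 3L)
  m <- sg_train(m, all)
  s1 <- summarize_attention(m, all)
  s2 <- summarize_attention(m, all)
  expect_identical(s1, s2)
  present <- s1$n_windows > 0
  expect_true(any(present))
  # temporal attention columns are probability vectors (center row of Q')
  ok <- colSums(s1$temporal_attention[, present, drop = FALSE])
  expect_equal(unname(ok), rep(1, sum(present)), tolerance = 1e-6)
  dir <- tempfile()
  export_attention(s1, dir)
  export_graphs(s1, dir)
  expect_true(file.exists(file.path(dir, "channel_attention.tsv")))
  expect_true(length(list.files(dir, pattern = "^adjacency_")) >= 1)
})
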