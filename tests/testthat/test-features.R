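test_that("differential entropy of white noise matches the Gaussian closed form", {
  fs <- 128
  mont <- sg_default_montage(2L)
  sig <- withr::with_seed(1, array(rnorm(2 * 30 * fs * 3), c(2, 30 * fs, 3)))
  rec <- sg_recording(sig, fs, c(0L, 1L, 2L), "s1", mont)
  # near-full band: variance ~ 1, DE ~ 0.5 log(2 pi e) = 1.4189
  de <- extract_de_features(rec, bands = list(wide = c(0.5, 60)))
  expect_equal(dim(de[[1]]), c(2L, 1L))
  expect_true(all(abs(unlist(de) - 0.5 * log(2 * pi * exp(1))) < 0.15))
})

test_that("a 10 Hz sinusoid has higher alpha-band than beta-band DE", {
  fs <- 128
  mont <- sg_default_montage(2L)
  tt <- (0:(30 * fs - 1)) / fs
  epoch <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 10 * tt + 1))
  sig <- array(epoch + withr::with_seed(2, rnorm(length(epoch), sd = 0.05)),
               c(2, 30 * fs, 1))
  rec <- sg_recording(sig, fs, 0L, "s1", mont)
  de <- extract_de_features(rec, bands = list(alpha = c(8, 13),
                                              beta = c(16, 30)))
  expect_true(all(de[[1]][, "alpha"] > de[[1]][, "beta"]))
})

test_that("DE extraction agrees with a direct filter+variance+log oracle", {
  fs <- 256
  mont <- sg_default_montage(2L)
  sig <- withr::with_seed(3, array(rnorm(2 * 30 * fs), c(2, 30 * fs, 1)))
  rec <- sg_recording(sig, fs, 2L, "s1", mont)
  bands <- list(theta = c(4, 8), beta = c(16, 30))
  de <- extract_de_features(rec, bands)
  for (j in seq_along(bands)) {
    bf <- signal::butter(4, bands[[j]] / (fs / 2), type = "pass")
    for (n in 1:2) {
      v <- var(signal::filtfilt(bf, sig[n, , 1]))
      expect_equal(de[[1]][n, j], 0.5 * log(2 * pi * exp(1) * v),
                   tolerance = 1e-8)
    }
  }
})

test_that("bands above Nyquist are rejected", {
  fs <- 64
  mont <- sg_default_montage(2L)
  sig <- array(rnorm(2 * 30 * fs), c(2, 30 * fs, 1))
  rec <- sg_recording(sig, fs, 0L, "s1", mont)
  expect_error(extract_de_features(rec, bands = list(c(30, 45))), "Nyquist")
})

test_that("context window construction counts and labels are exact", {
  N <- 3L; Fd <- 2L
  feats <- lapply(1:10, function(i) matrix(i, N, Fd))
  # L = 10, d = 2 -> 6 windows centred on epochs 3..8 (1-based)
  w <- build_context_windows(feats, labels = 0:9 %% 5, subject_id = "s", d = 2L)
  expect_equal(dim(w$x)[4], 6L)
  expect_equal(w$center, 3:8)
  expect_equal(w$y, (2:7) %% 5)
  expect_equal(w$x[1, 1, , 1], 1:5)          # oldest -> newest ordering
  # d = 0 -> L windows of Tn = 1
  w0 <- build_context_windows(feats, labels = rep(0L, 10), subject_id = "s",
                              d = 0L)
  expect_equal(dim(w0$x)[3:4], c(1L, 10L))
  # L = 5, d = 2 -> single window labeled with the center epoch's label
  w1 <- build_context_windows(feats[1:5], labels = 0:4, subject_id = "s",
                              d = 2L)
  expect_equal(dim(w1$x)[4], 1L)
  expect_equal(w1$y, 2L)
  expect_error(build_context_windows(feats[1:4], labels = rep(0L, 4),
                                     subject_id = "s", d = 2L), "L = 4")
})

test_that("window count L - 2d holds over random L, d", {
  withr::with_seed(42, {
    for (i in 1:20) {
      d <- sample(0:4, 1)
      L <- sample((2 * d + 1):(2 * d + 20), 1)
      feats <- lapply(seq_len(L), function(i) matrix(rnorm(4), 2, 2))
      w <- build_context_windows(feats, labels = rep(0L, L), subject_id = "s",
                                 d = d)
      expect_equal(dim(w$x)[4], L - 2 * d)
    }
  })
})

test_that("standardization centers, scales, leaves constants alone, and is idempotent", {
  w <- tiny_windows()
  all <- bind_windows(w)
  s1 <- standardize_features(all)
  m <- apply(s1$x, c(1, 2), mean)
  v <- apply(s1$x, c(1, 2), function(z) var(as.vector(z)))
  expect_true(max(abs(m)) < 1e-10)
  expect_true(max(abs(v - 1)) < 1e-6)
  # idempotence with the same stats
  s2 <- standardize_features(s1, attr(s1, "stats"))
  st0 <- attr(s1, "stats")
  expect_equal(s2$x,
               (s1$x - array(st0$mean, dim(s1$x))) / array(st0$sd, dim(s1$x)))
  # affine invariance: a* x + b standardizes to the same output (a > 0)
  sh <- all
  sh$x <- 3 * all$x + 2
  expect_equal(standardize_features(sh)$x, s1$x, tolerance = 1e-10)
  # constant feature left unscaled with a warning
  cw <- all
  cw$x[1, 1, , ] <- 5
  expect_warning(st <- compute_feature_stats(cw), "constant")
  out <- standardize_features(cw, st)
  expect_equal(out$x[1, 1, , ], cw$x[1, 1, , ])
})

test_that("train-set statistics applied to held-out windows leak nothing", {
  w <- tiny_windows()
  stats <- compute_feature_stats(w[[1]])
  te <- standardize_features(w[[2]], stats)
  # held-out windows are transformed by the training map, not their own
  expect_false(isTRUE(all.equal(apply(te$x, c(1, 2), mean) * 0,
                                apply(te$x, c(1, 2), mean))))
  expect_identical(attr(te, "stats"), stats)
})
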