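test_that("identical features or zero weights give the exact uniform adjacency", {
  X <- matrix(1.7, 5, 3)
  A <- learn_fc_adjacency(X, w = c(1, 2, 3))
  expect_equal(A, matrix(1 / 5, 5, 5))
  X2 <- matrix(rnorm(15), 5, 3)
  expect_equal(learn_fc_adjacency(X2, w = rep(0, 3)), matrix(1 / 5, 5, 5))
})

test_that("3-node learned adjacency matches direct evaluation", {
  X <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  w <- c(1, 1)
  A <- learn_fc_adjacency(X, w)
  expect_equal(A, oracle_fc_adjacency(X, w), tolerance = 1e-10)
  expect_equal(rowSums(A), rep(1, 3))
})

test_that("adjacency is row-stochastic with entries in (0, 1] for random inputs", {
  withr::with_seed(11, {
    for (i in 1:25) {
      N <- sample(2:8, 1); Fd <- sample(1:6, 1)
      X <- matrix(rnorm(N * Fd, sd = runif(1, 0.1, 10)), N, Fd)
      A <- learn_fc_adjacency(X, rnorm(Fd))
      expect_equal(rowSums(A), rep(1, N), tolerance = 1e-12)
      expect_true(all(A > 0 & A <= 1))
    }
  })
})

test_that("graph-learning loss: degenerate closed form and brute-force agreement", {
  # identical features, uniform adjacency: loss = lambda * ||A||_F^2 = lambda
  N <- 4
  X <- matrix(2, N, 3)
  A <- learn_fc_adjacency(X, rep(1, 3))
  expect_equal(graph_learning_loss(X, A), 0.001)
  X2 <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  A2 <- learn_fc_adjacency(X2, c(1, 1))
  expect_equal(graph_learning_loss(X2, A2, 0.001),
               oracle_graph_loss(X2, A2, 0.001), tolerance = 1e-10)
  # strictly increasing in lambda
  expect_gt(graph_learning_loss(X2, A2, 0.01), graph_learning_loss(X2, A2, 0.001))
  expect_error(graph_learning_loss(X2, A2, -1), "non-negative")
})

test_that("gradient of the graph loss through the adjacency matches finite differences", {
  withr::with_seed(5, {
    for (rep in 1:3) {
      N <- 4; Fd <- 3
      X <- matrix(rnorm(N * Fd), N, Fd)
      w <- runif(Fd, 0.2, 1)
      lam <- 0.001
      # analytic gradient via the engine's batched machinery
      sg <- asNamespace("sleepgcn")
      PD <- array(0, c(N, N, Fd, 1)); D2 <- array(0, c(N, N, 1))
      for (m in 1:N) for (n in 1:N) {
        PD[m, n, , 1] <- abs(X[m, ] - X[n, ])
        D2[m, n, 1] <- sum((X[m, ] - X[n, ])^2)
      }
      fg <- sg$fc_graph_fwd(w, PD, K = 1L)
      dA <- D2 + 2 * lam * fg$A
      g <- sg$fc_graph_bwd(fg$cache, array(dA, c(N, N, 1)), NULL)
      num <- vapply(seq_len(Fd), function(j) {
        h <- 1e-6
        wp <- w; wp[j] <- wp[j] + h
        wm <- w; wm[j] <- wm[j] - h
        (graph_learning_loss(X, learn_fc_adjacency(X, wp), lam) -
           graph_learning_loss(X, learn_fc_adjacency(X, wm), lam)) / (2 * h)
      }, 0)
      expect_equal(g, num, tolerance = 1e-5)
    }
  })
})

test_that("distance adjacency matches the pairwise-distance kernel", {
  # antipodal electrodes at distance 2: single off-diagonal weight exp(-2)
  m2 <- sg_montage(c("A", "B"), rbind(c(0, 0, 1), c(0, 0, -1)))
  A <- build_distance_adjacency(m2, sigma = 1, threshold = 0)
  expect_equal(A[1, 2], exp(-2))
  expect_equal(diag(A), c(A = 0, B = 0))
  # three orthogonal unit electrodes: all pairs at distance sqrt(2)
  m3 <- sg_montage(c("A", "B", "C"), diag(3))
  A3 <- build_distance_adjacency(m3, sigma = 1, threshold = 0)
  expect_equal(A3[upper.tri(A3)], rep(exp(-1), 3))
  # aggressive threshold disconnects the graph with a warning
  expect_warning(A0 <- build_distance_adjacency(m3, sigma = 1, threshold = 0.99),
                 "no edges")
  expect_true(all(A0 == 0))
})

test_that("distance adjacency is invariant under global rotation of the montage", {
  mont <- sg_default_montage(6L)
  th <- 0.9
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sg_montage(mont$names, mont$coords %*% t(Rz))
  expect_equal(unname(build_distance_adjacency(mont)),
               unname(build_distance_adjacency(rot)), tolerance = 1e-12)
})

test_that("scaled Laplacian has spectrum in [-1, 1] and known 2-node form", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  Lt <- scaled_laplacian(A)
  expect_equal(unclass(Lt), matrix(c(0, -1, -1, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(Lt, "lambda_max"), 2)
  expect_warning(Lz <- scaled_laplacian(matrix(0, 3, 3)), "all-zero")
  expect_equal(unclass(Lz), -diag(3), ignore_attr = TRUE)
  withr::with_seed(8, {
    for (i in 1:10) {
      N <- 6
      M <- matrix(runif(N * N), N, N)
      A <- (M + t(M)) / 2
      diag(A) <- 0
      ev <- eigen(scaled_laplacian(A), symmetric = TRUE, only.values = TRUE)$values
      expect_true(max(abs(ev)) <= 1 + 1e-6)
    }
  })
})

test_that("Chebyshev polynomial basis follows the recursion", {
  Lt <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_equal(cheb_polynomials(Lt, 1), list(diag(2)))
  expect_equal(cheb_polynomials(Lt, 2), list(diag(2), Lt))
  # T_2 = 2 Lt^2 - I = I for this Lt
  cb <- cheb_polynomials(Lt, 3)
  expect_equal(cb[[3]], 2 * Lt %*% Lt - diag(2))
  expect_equal(cb[[3]], diag(2))
  expect_error(cheb_polynomials(Lt, 0), "K")
})

test_that("fixed adjacency baselines behave per definition", {
  expect_equal(fixed_adjacency("full", n = 4), matrix(1, 4, 4))
  # identical sinusoids: PLV exactly 1
  tt <- seq(0, 2, by = 0.01)
  X <- rbind(sin(2 * pi * 5 * tt), sin(2 * pi * 5 * tt))
  plv <- fixed_adjacency("plv", X)
  expect_equal(plv[1, 2], 1, tolerance = 1e-8)
  # pcc matches cor() on a seeded series
  Xs <- withr::with_seed(4, matrix(rnorm(3 * 200), 3, 200))
  expect_equal(unname(fixed_adjacency("pcc", Xs)), abs(cor(t(Xs))),
               tolerance = 1e-10)
  # constant channel: correlation defined as 0 with warning
  Xc <- Xs; Xc[2, ] <- 1
  expect_warning(pc <- fixed_adjacency("pcc", Xc), "constant")
  expect_equal(pc[1, 2], 0)
  # knn keeps k neighbours per row, symmetrized by max
  kn <- fixed_adjacency("knn", Xs, k = 1)
  expect_true(all(kn %in% c(0, 1)))
  expect_equal(kn, pmax(kn, t(kn)))
  expect_error(fixed_adjacency("knn", Xs, k = 3), "k < N")
  # mutual information: symmetric, scaled to [0, 1]
  mi <- fixed_adjacency("mi", Xs)
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0 & mi <= 1))
  expect_equal(max(mi), 1)
})

test_that("adjacency export writes a labelled square table", {
  A <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("F3", "C3"),
                                                       c("F3", "C3")))
  f <- tempfile(fileext = ".tsv")
  export_adjacency(A, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(tab$channel, c("F3", "C3"))
  expect_equal(as.matrix(tab[, -1]), A, ignore_attr = TRUE)
})
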