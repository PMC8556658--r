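test_that("gradient reversal is the exact identity forward and -beta backward", {
  x <- c(-1.5, 0, 2.25)
  expect_identical(gradient_reversal(x, 0.5), x)
  expect_identical(gradient_reversal(x, 0), x)
  expect_equal(grl_backward(c(1, -2), 0.5), c(-0.5, 1))
  expect_equal(grl_backward(c(1, -2), 0), c(0, 0))
  expect_error(gradient_reversal(x, -1), "beta")
})

test_that("scalar chain through the GRL matches finite differences", {
  # f(x) = x through the GRL into g(z) = z^2; the reversed objective seen
  # by x is -beta * z^2, so dL/dx = -beta * 2x
  beta <- 0.7
  x <- 1.3
  ana <- grl_backward(2 * x, beta)
  h <- 1e-6
  num <- (-beta * (x + h)^2 - (-beta * (x - h)^2)) / (2 * h)
  expect_equal(ana, num, tolerance = 1e-6)
})

test_that("head predictions are simplex vectors with softmax properties", {
  p <- 6L
  heads <- list(wy = matrix(0, 5, p), by = rep(0, 5),
                wh = withr::with_seed(1, matrix(rnorm(4 * p), 4, p)),
                bh = rep(0, 4),
                wd = withr::with_seed(2, matrix(rnorm(3 * 4), 3, 4)),
                bd = rep(0, 3))
  f <- withr::with_seed(3, rnorm(p))
  pr <- predict_heads(f, heads)
  expect_equal(pr$y_hat, rep(1 / 5, 5))          # zero logits -> uniform
  expect_equal(sum(pr$d_hat), 1)
  expect_true(all(pr$d_hat > 0))
  # shift invariance of the softmax
  heads2 <- heads
  heads2$by <- heads2$by + 7
  expect_equal(predict_heads(f, heads2)$y_hat, pr$y_hat)
  # direct exponentiation oracle
  heads3 <- heads
  heads3$wy <- withr::with_seed(4, matrix(rnorm(5 * p), 5, p))
  z <- drop(heads3$wy %*% f)
  expect_equal(predict_heads(f, heads3)$y_hat, exp(z) / sum(exp(z)),
               tolerance = 1e-10)
})

test_that("cross entropy closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0)
  expect_equal(cross_entropy(rep(1 / 7, 7), 3), log(7))
  # batch of 3 hand-computed predictions
  pred <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.25, 0.25, 0.5))
  want <- mean(-log(c(0.7, 0.8, 0.5)))
  expect_equal(cross_entropy(pred, c(1, 2, 3)), want)
  expect_warning(v <- cross_entropy(c(1, 0), 2), "clamped")
  expect_equal(v, -log(1e-12))
})

test_that("total loss is reproducible component arithmetic", {
  rep <- total_loss(0.4, log(5), 10, beta = 0.5, gamma = 1e-4)
  expect_equal(rep$loss_total, 0.4 + log(5) + 1e-4 * 10)
  rep0 <- total_loss(0.4, 0, 0, beta = 0, gamma = 0)
  expect_equal(rep0$loss_total, 0.4)
})

test_that("full-model analytic gradients match central finite differences", {
  sg <- asNamespace("sleepgcn")
  withr::with_seed(42, {
    N <- 4L; Fd <- 3L; Tn <- 3L; B <- 5L
    config <- sg_config(d = 1L, K = 3L, channels = 4L, beta = 0.7,
                        gamma = 0.05, seed = 7L, n_classes = 3L)
    model <- build_model(config, sg_default_montage(N), Fd = Fd,
                         n_domains = 2L)
    params <- model$params
    X <- array(rnorm(N * Fd * Tn * B), c(N, Fd, Tn, B))
    y <- sample.int(3L, B, replace = TRUE)
    dom <- sample.int(2L, B, replace = TRUE)
    tc <- 2L
    PDb <- array(0, c(N, N, Fd, B)); D2b <- array(0, c(N, N, B))
    for (b in seq_len(B)) for (m in 1:N) for (n in 1:N) {
      PDb[m, n, , b] <- abs(X[m, , tc, b] - X[n, , tc, b])
      D2b[m, n, b] <- sum((X[m, , tc, b] - X[n, , tc, b])^2)
    }
    fwd <- sg$model_fwd(params, X, config, model$fixed_cheb, PDb, D2b)
    grads <- sg$model_bwd(params, X, config, fwd, y, dom, NULL, D2b)
    # the GRL realizes the saddle objective: head parameters minimize
    # loss_y + loss_d + gamma * graph; shared parameters see the domain
    # term reversed (-beta)
    objective <- function(p, sign_d) {
      f <- sg$model_fwd(p, X, config, model$fixed_cheb, PDb, D2b)
      ls <- sg$batch_losses(f, y, dom, NULL, config$domain_smooth)
      ls$loss_y + sign_d * ls$loss_d + config$gamma * ls$loss_graph
    }
    fl <- sg$flatten_params(params)
    fg <- sg$flatten_params(grads)
    h <- 1e-5
    for (key in names(fg)) {
      sgn <- if (key %in% c("wh", "bh", "wd", "bd")) 1 else -config$beta
      g <- fg[[key]]
      idx <- sample(length(g), min(3, length(g)))
      path <- strsplit(key, "$", fixed = TRUE)[[1]]
      for (i in idx) {
        v <- fl[[key]]
        v[i] <- v[i] + h
        up <- objective(sg$assign_path(params, path, v), sgn)
        v[i] <- v[i] - 2 * h
        dn <- objective(sg$assign_path(params, path, v), sgn)
        num <- (up - dn) / (2 * h)
        expect_equal(g[i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", key, i))
      }
    }
  })
})
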