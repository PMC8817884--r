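test_that("convolution geometry and values match hand-enumerated oracles", {
  # identity kernel with padding: interior preserved
  x <- matrix(withr::with_seed(1, rnorm(36)), 6, 6)
  kid <- matrix(0, 3, 3); kid[2, 2] <- 1
  out <- conv_forward(x, kid, activation = "linear", padding = 1)
  expect_equal(dim(out), c(6L, 6L))
  expect_equal(out, x)
  # all-ones 2x2 kernel, stride 2, no padding: block sums
  x4 <- matrix(1:16, 4, 4, byrow = TRUE)
  out2 <- conv_forward(x4, matrix(1, 2, 2), activation = "linear",
                       stride = 2)
  expect_equal(out2, matrix(c(1 + 2 + 5 + 6, 3 + 4 + 7 + 8,
                              9 + 10 + 13 + 14, 11 + 12 + 15 + 16),
                            2, 2, byrow = TRUE))
  # 24x24, 3x3, stride 1, pad 1 keeps 24x24 and applies ReLU
  x24 <- matrix(withr::with_seed(2, rnorm(576)), 24, 24)
  k <- array(withr::with_seed(3, rnorm(9 * 16)), c(3, 3, 1, 16))
  o24 <- conv_forward(x24, k, padding = 1)
  expect_equal(dim(o24), c(24L, 24L, 16L))
  expect_true(all(o24 >= 0))
  expect_error(conv_forward(x4, matrix(1, 3, 3), stride = 2), "divisible")
})

test_that("max pooling halves sides and takes block maxima", {
  x4 <- matrix(1:16, 4, 4, byrow = TRUE)
  out <- max_pool(x4, 2, 2)
  expect_equal(out, matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  x24 <- array(withr::with_seed(4, rnorm(24 * 24 * 16)), c(24, 24, 16))
  expect_equal(dim(max_pool(x24)), c(12L, 12L, 16L))
  cst <- matrix(7, 6, 6)
  expect_equal(max_pool(cst), matrix(7, 3, 3))
})

test_that("self-attention: identity, uniform keys, arithmetic oracle", {
  d <- 4
  Wq <- diag(d); Wk <- diag(d); Wv <- diag(d)
  x1 <- matrix(rnorm(d), 1, d)
  out1 <- self_attention(x1, Wq, Wk, Wv)
  expect_equal(unname(out1[1, ]), unname((x1 %*% Wv)[1, ]))
  # identical keys (zero W_k) -> uniform weights -> mean of value vectors
  X <- matrix(withr::with_seed(5, rnorm(6 * d)), 6, d)
  outU <- self_attention(X, Wq, matrix(0, d, d), Wv)
  W <- attr(outU, "weights")
  expect_equal(unname(W), matrix(1 / 6, 6, 6), tolerance = 1e-12)
  expect_equal(unname(outU[1, ]), unname(colMeans(X %*% Wv)))
  # two tokens, 2-d, scalar-by-scalar evaluation
  X2 <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE)
  Wq2 <- matrix(c(1, 0, 0, 1), 2); Wk2 <- matrix(c(0.5, 0, 0, 0.5), 2)
  Wv2 <- matrix(c(2, 0, 0, 2), 2)
  out2 <- self_attention(X2, Wq2, Wk2, Wv2, d_k = 2)
  Q <- X2 %*% Wq2; K <- X2 %*% Wk2; V <- X2 %*% Wv2
  S <- (Q %*% t(K)) / sqrt(2)
  e1 <- exp(S[1, ]); a1 <- e1 / sum(e1)
  expect_equal(unname(out2[1, ]), unname(a1[1] * V[1, ] + a1[2] * V[2, ]),
               tolerance = 1e-12)
  expect_error(self_attention(X, Wq[, 1:2], Wk, Wv), "same dimension")
  expect_error(self_attention(X, diag(3), diag(3), diag(3)), "rows")
})

test_that("attention weights are row-stochastic convex combinations", {
  for (s in 1:10) {
    n <- withr::with_seed(600 + s, sample(2:64, 1))
    d <- withr::with_seed(700 + s, sample(2:8, 1))
    X <- withr::with_seed(800 + s, matrix(rnorm(n * d), n, d))
    Wq <- withr::with_seed(900 + s, matrix(rnorm(d * d), d, d))
    out <- self_attention(X, Wq, Wq[, d:1, drop = FALSE], diag(d))
    W <- attr(out, "weights")
    expect_equal(unname(rowSums(W)), rep(1, n), tolerance = 1e-9)
    expect_true(all(W >= 0))
  }
})

test_that("residual blocks: zero residual is identity, identity doubles", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(residual_block(x, function(z) z * 0), x)
  expect_equal(residual_block(x, identity), 2 * x)
  # two stacked blocks match the explicit summation form
  f1 <- function(z) 0.5 * z; f2 <- function(z) z + 1
  manual <- x + f1(x) + f2(x + f1(x))
  expect_equal(residual_block(residual_block(x, f1), f2), manual)
  expect_error(residual_block(x, function(z) z[1:2, ]), "shape")
})

test_that("autoencoder recovers an exact linear subspace and is monotone", {
  # data on a 3-dimensional subspace of R^10
  B <- withr::with_seed(11, matrix(rnorm(30), 10, 3))
  Z <- withr::with_seed(12, matrix(rnorm(600), 200, 3))
  X <- Z %*% t(B)
  ae <- autoencoder_pretrain(X, 3, epochs = 50, seed = 1)
  rel <- ae$loss[length(ae$loss)] / mean(X^2)
  expect_lt(rel, 1e-3)
  expect_true(all(diff(ae$loss) <= 1e-12))
  # determinism under a fixed seed
  ae2 <- autoencoder_pretrain(X, 3, epochs = 50, seed = 1)
  expect_identical(ae$loss, ae2$loss)
  expect_error(autoencoder_pretrain(X, 10), "smaller")
  expect_error(autoencoder_pretrain(X, 12), "smaller")
})

test_that("the forward shape trace reproduces the reference stack", {
  sh <- forward_shapes(network_config())
  expect_equal(sh$out_side, c(24, 12, 12, 6, 6, 3))
  expect_equal(sh$maps, c(16, 16, 32, 32, 64, 64))
  expect_equal(attr(sh, "flatten"), 576)
  expect_equal(attr(sh, "flatten"), 3 * 3 * 64)
  # a misconfigured layer names itself in the error
  bad <- network_config()
  bad$layers[[1]]$stride <- 5L
  expect_error(forward_shapes(bad), "layer 1")
})

test_that("forward pass is bounded, finite and constant under zero weights", {
  cfg <- network_config(seed = 3)
  m <- build_network(cfg)
  x <- matrix(withr::with_seed(13, rnorm(5 * 576)), 5, 576)
  y <- predict_network(m, x)
  expect_true(all(is.finite(y)))
  expect_true(all(y >= 0 & y <= 100))
  mz <- m
  for (nm in names(mz$params)) mz$params[[nm]][] <- 0
  yz <- predict_network(mz, x)
  expect_equal(yz, rep(yz[1], 5))
  # zeroed residual branch passes the identity through the block
  mr <- m; mr$params$Wr[] <- 0; mr$params$br[] <- 0
  h <- eegdepth:::stack_forward(mr, x[1, , drop = FALSE])$H
  hf <- eegdepth:::head_forward(mr, h, keep = TRUE)
  expect_equal(hf$cache$H2, h)
})

test_that("analytic gradients match finite differences", {
  m <- build_network(network_config(seed = 5))
  x <- matrix(withr::with_seed(14, rnorm(2 * 576)), 2, 576)
  y <- c(40, 70)
  lg <- eegdepth:::network_loss_grad(m, x, y)
  eps <- 1e-5
  for (nm in c("W1", "W3", "Wq", "Wv", "Wr", "Wo", "b5", "bo")) {
    i <- withr::with_seed(nchar(nm) + match(nm, names(m$params)),
                          sample(length(m$params[[nm]]), 1))
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    g_num <- (eegdepth:::network_loss_grad(mp, x, y)$loss -
                eegdepth:::network_loss_grad(mm, x, y)$loss) / (2 * eps)
    g_an <- lg$grads[[nm]][i]
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
})

test_that("training bookkeeping: schedules, checkpoints, determinism", {
  set <- tiny_sample_set(n = 48, seed = 7)
  val <- tiny_sample_set(n = 16, seed = 8)
  cfg <- network_config(seed = 2, batch_size = 8)
  r <- train_network(set, cfg, val = val,
                     schedule = list(periods = 2, iters_per_period = 45))
  expect_equal(nrow(r$log), 90)
  expect_equal(r$checkpoints, c(30, 60, 90))
  expect_equal(unique(r$log$period), c(1, 2))
  expect_true(all(is.finite(r$log$loss)))
  expect_true(all(is.na(r$log$val_accuracy[setdiff(1:90, r$checkpoints)])))
  # bit-reproducible under the same seed
  r2 <- train_network(set, cfg, val = val,
                      schedule = list(periods = 2, iters_per_period = 45))
  expect_identical(r$log, r2$log)
  expect_identical(r$model$params, r2$model$params)
  expect_error(train_network(set, cfg, schedule = list(periods = 0,
                                                       iters_per_period = 5)),
               "schedule")
})

test_that("training loss decreases on a linear toy target", {
  set <- tiny_sample_set(n = 80, seed = 9)
  # plain gradient descent isolates the convergence property from
  # momentum overshoot and the weight-decay floor
  cfg <- network_config(seed = 4, batch_size = 16, momentum = 0,
                        weight_decay = 0)
  r <- train_network(set, cfg,
                     schedule = list(periods = 1, iters_per_period = 300))
  sm <- stats::filter(r$log$loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_lt(mean(tail(r$log$loss, 20)), mean(head(r$log$loss, 20)))
})

test_that("cross-validated training is subject-level and finds best/worst", {
  set <- tiny_sample_set(n = 60, seed = 10, n_subjects = 6)
  cfg <- network_config(seed = 6, batch_size = 8)
  cv <- train_model(set, cfg, folds = 3,
                    schedule = list(periods = 1, iters_per_period = 20))
  expect_length(cv$folds, 3)
  expect_true(cv$best %in% 1:3 && cv$worst %in% 1:3)
  expect_lte(cv$folds[[cv$worst]]$final_accuracy,
             cv$folds[[cv$best]]$final_accuracy)
  held <- unlist(cv$fold_subjects)
  expect_setequal(held, unique(set$subject_id))
  expect_false(any(duplicated(held)))
  expect_error(train_model(set, cfg, folds = 10), "folds")
})
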