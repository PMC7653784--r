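test_that("the full preset reproduces the 227 dimension chain", {
  arch <- network_preset("full", class_count = 4)
  net <- build_network(arch, c("top_view", "side_view", "irregular",
                               "background"), seed = 1)
  expect_equal(network_dims(net), c(55, 27, 27, 13, 13, 13, 13, 6))
  fc <- Filter(function(l) l$type == "fc", net$layers)
  expect_equal(vapply(fc, function(l) l$units, numeric(1)), c(4096, 4096, 4))
  net2 <- build_network(arch, c("a", "b", "c", "d"), seed = 1)
  expect_identical(net$layers[[1]]$W, net2$layers[[1]]$W)
  expect_error(build_network(arch, c("a", "b"), seed = 1), "class names")
})

test_that("sigmoid saturates safely and is symmetric", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(1, 5, 20)) expect_equal(sigmoid(-x), 1 - sigmoid(x))
  expect_equal(sigmoid(-1000), 0)
  expect_equal(sigmoid(1000), 1)
  expect_false(any(!is.finite(sigmoid(c(-1e4, 1e4)))))
})

test_that("conv_forward matches a naive triple-loop reference", {
  arch <- list(input_size = 7, channels = 2, layers = list(
    list(type = "conv", filters = 3, k = 3, stride = 1, pad = 1),
    list(type = "fc", units = 2, activation = "softmax")))
  net <- build_network(arch, c("a", "b"), seed = 2)
  lay <- net$layers[[1]]
  set.seed(42)
  x <- array(stats::runif(7 * 7 * 2), c(7, 7, 2))
  expect_equal(conv_forward(x, lay),
               naive_conv(x, lay$W, lay$b, 3, 1, 1, 2, 3),
               tolerance = 1e-6)
  # identity kernel leaves the pre-activation input unchanged
  id <- lay
  id$W[] <- 0
  id$W[5, ] <- 1  # center tap of channel 1 (dy0=1, dx0=1 in column order)
  id$b[] <- 0
  pre <- conv_forward(x, id, pre_activation = TRUE)
  expect_equal(pre[, , 1], x[, , 1], tolerance = 1e-12)
  # zero weights and bias give sigmoid(0) = 0.5 everywhere
  z <- lay; z$W[] <- 0; z$b[] <- 0
  expect_true(all(conv_forward(x, z) == 0.5))
  expect_error(conv_forward(array(0, c(5, 5, 2)), lay), "shape")
})

test_that("maxpool_forward matches a brute-force window scan", {
  set.seed(9)
  x <- array(stats::runif(4 * 4 * 2), c(4, 4, 2))
  out <- maxpool_forward(x, 2, 2)
  expect_equal(as.vector(out), as.vector(naive_pool(x, 2, 2)))
  const <- array(0.3, c(6, 6, 1))
  expect_true(all(maxpool_forward(const, 3, 2) == 0.3))
  # 55 -> 27 with kernel 3 stride 2
  big <- array(0, c(55, 55, 1))
  expect_equal(dim(maxpool_forward(big, 3, 2))[1], 27)
  expect_error(maxpool_forward(x, 10, 1), "larger than input")
  # mean mode variant
  expect_equal(as.vector(maxpool_forward(const, 2, 2, mode = "mean")),
               rep(0.3, 9))
})

test_that("cross-entropy loss matches the scalar-loop definition", {
  expect_equal(cross_entropy_loss(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                  matrix(c(1, 0, 0, 1), 2, byrow = TRUE)), 0)
  u <- matrix(0.25, 1, 4)
  y <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(cross_entropy_loss(u, y), log(4))
  set.seed(3)
  p <- matrix(stats::runif(20), 5)
  p <- p / rowSums(p)
  yy <- diag(4)[sample(4, 5, replace = TRUE), ]
  manual <- 0
  for (i in 1:5) for (c in 1:4) manual <- manual - yy[i, c] * log(p[i, c])
  expect_equal(cross_entropy_loss(p, yy), manual, tolerance = 1e-9)
  # zero probability at the true class is clamped, not -Inf
  p0 <- matrix(c(0, 1, 0, 0), 1)
  expect_true(is.finite(cross_entropy_loss(p0, matrix(c(1, 0, 0, 0), 1))))
})

test_that("analytic gradients match central differences on a toy net", {
  arch <- list(input_size = 8, channels = 1, layers = list(
    list(type = "conv", filters = 2, k = 3, stride = 1, pad = 0),
    list(type = "pool", k = 2, stride = 2),
    list(type = "fc", units = 5),
    list(type = "fc", units = 3, activation = "softmax")))
  net <- build_network(arch, c("a", "b", "c"), seed = 3)
  set.seed(4)
  x <- array(stats::runif(64), c(8, 8, 1))
  y <- c(0, 1, 0)
  fw <- cryopickr:::forward_net(net, x, keep = TRUE)
  g <- cryopickr:::backward_net(net, fw$cache, y)
  eps <- 1e-5
  for (li in c(1, 3, 4)) {
    W <- net$layers[[li]]$W
    for (t in 1:15) {
      i <- sample(length(W), 1)
      np <- net; np$layers[[li]]$W[i] <- W[i] + eps
      nm <- net; nm$layers[[li]]$W[i] <- W[i] - eps
      lp <- -sum(y * log(cryopickr:::forward_net(np, x)$prob))
      lm <- -sum(y * log(cryopickr:::forward_net(nm, x)$prob))
      num <- (lp - lm) / (2 * eps)
      ana <- g[[li]]$W[i]
      if (abs(num) > 1e-8)
        expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4)
    }
  }
})

test_that("sgd_step applies the eta/N update and rejects bad gradients", {
  arch <- list(input_size = 4, channels = 1, layers = list(
    list(type = "fc", units = 2, activation = "softmax")))
  net <- build_network(arch, c("a", "b"), seed = 1)
  zero <- list(list(W = net$layers[[1]]$W * 0, b = net$layers[[1]]$b * 0))
  same <- sgd_step(net, zero, 0.1, 4)
  expect_identical(same$layers[[1]]$W, net$layers[[1]]$W)
  g1 <- list(list(W = net$layers[[1]]$W * 0 + 2, b = net$layers[[1]]$b))
  upd <- sgd_step(net, g1, learning_rate = 1, n = 2)
  expect_equal(upd$layers[[1]]$W, net$layers[[1]]$W - 1)
  gbad <- list(list(W = net$layers[[1]]$W * NaN, b = net$layers[[1]]$b))
  expect_error(sgd_step(net, gbad, 0.1, 1), "non-finite")
})

test_that("training on the separable 4-class set reaches 95% validation", {
  fit <- toy_fit()
  hist <- tidy(fit)
  expect_equal(nrow(hist), 20)
  expect_gte(hist$val_acc[20], 0.95)
  # loss decreases overall; upticks bounded by 5% of the initial loss
  expect_true(all(diff(hist$loss) <= 0.05 * hist$loss[1]))
  expect_lt(hist$loss[20], 0.25 * hist$loss[1])
  g <- glance(fit)
  expect_equal(g$epochs, 20)
  expect_gt(g$n_parameters, 0)
})

test_that("training is reproducible under a fixed seed", {
  split <- toy_split()
  sub <- split[split$split %in% c("train", "val"), ]
  sub <- sub[sub$label %in% c("top_view", "background"), ]
  f1 <- train_cnn(sub, epochs = 2, batch_size = 16, learning_rate = 0.3,
                  seed = 7)
  f2 <- train_cnn(sub, epochs = 2, batch_size = 16, learning_rate = 0.3,
                  seed = 7)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_error(train_cnn(split[0, ], epochs = 1), "empty")
})

test_that("patch prediction returns normalized, deterministic probabilities", {
  fit <- toy_fit()
  split <- toy_split()
  test_rows <- split[split$split == "test", ]
  p <- predict_patch(fit, test_rows$patch[[1]])
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_patch(fit, test_rows$patch[[1]]))
  expect_error(predict_patch(fit, matrix(0, 8, 8)), "expects")
  # held-out accuracy: the argmax class matches the label almost always
  idx <- seq(1, nrow(test_rows), by = 4)
  correct <- vapply(idx, function(i)
    names(which.max(predict_patch(fit, test_rows$patch[[i]]))) ==
      test_rows$label[i], logical(1))
  expect_gte(mean(correct), 0.9)
})
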