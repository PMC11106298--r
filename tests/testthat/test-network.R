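test_that("weight-vector dimensionality follows the layer-count formula", {
  expect_identical(network_dimension(network_shape(4, 5, 1)), 31L)
  expect_identical(network_dimension(network_shape(1, 1, 1)), 4L)
  expect_identical(network_dimension(network_shape(7, 5, 1)), 46L)
  expect_error(network_shape(0, 5, 1))
})

test_that("encode and decode are exact inverses with the documented layout", {
  shape <- network_shape(4, 5, 1)
  v <- as.numeric(1:31)
  net <- decode_weights(v, shape)
  expect_equal(net$W1[1, 1], 1)
  expect_equal(net$W1[1, ], 1:5, ignore_attr = TRUE)  # W1 row-major
  expect_equal(net$b1, 21:25, ignore_attr = TRUE)
  expect_equal(net$W2[, 1], 26:30, ignore_attr = TRUE)
  expect_equal(net$b2, 31)
  expect_identical(encode_weights(net), v)

  set.seed(5)
  for (i in 1:20) {
    shape <- network_shape(sample(1:8, 1), sample(1:8, 1), sample(1:3, 1))
    v <- rnorm(network_dimension(shape))
    expect_identical(encode_weights(decode_weights(v, shape)), v)
  }
  expect_error(decode_weights(1:5, network_shape(4, 5, 1)), "length")
})

test_that("forward pass matches hand-evaluated sigmoid compositions", {
  zero <- decode_weights(rep(0, 4), network_shape(1, 1, 1))
  expect_equal(as.numeric(nn_forward(zero, matrix(c(-3, 0, 42)))),
               rep(0.5, 3))
  # single unit: W1=0, b1=0 -> hidden 0.5; W2=4, b2=-2 -> sigmoid(0) = 0.5
  net <- network(matrix(0), 0, matrix(4), -2)
  expect_equal(as.numeric(nn_forward(net, matrix(1.7))), 0.5)
  # against a plain R evaluation on a random network
  set.seed(8)
  shape <- network_shape(3, 5, 1)
  net <- decode_weights(runif(network_dimension(shape), -1, 1), shape)
  X <- matrix(rnorm(30), 10, 3)
  manual <- plogis(plogis(sweep(X %*% net$W1, 2, net$b1, "+")) %*%
                     net$W2 + net$b2[1])
  expect_equal(as.numeric(nn_forward(net, X)), as.numeric(manual))
  expect_error(nn_forward(net, matrix(NA_real_, 1, 3)), "non-finite")
  expect_error(nn_forward(net, matrix(1, 1, 2)), "columns")
})

test_that("outputs stay strictly inside (0,1) even for extreme weights", {
  shape <- network_shape(2, 3, 1)
  big <- decode_weights(rep(1e6, network_dimension(shape)), shape)
  out <- nn_forward(big, matrix(c(1e3, -1e3, 1e3, -1e3), 2, 2))
  expect_true(all(out > 0 & out < 1))
  small <- decode_weights(rep(-1e6, network_dimension(shape)), shape)
  out <- nn_forward(small, matrix(c(1e3, -1e3, 1e3, -1e3), 2, 2))
  expect_true(all(out > 0 & out < 1))
})

test_that("output is monotone in the output bias", {
  set.seed(9)
  shape <- network_shape(3, 4, 1)
  net <- decode_weights(rnorm(network_dimension(shape)), shape)
  X <- matrix(rnorm(15), 5, 3)
  base <- nn_forward(net, X)
  for (db in c(0.1, 1, 10)) {
    up <- net
    up$b2 <- net$b2 + db
    expect_true(all(nn_forward(up, X) >= base))
  }
})

test_that("mean squared error matches its definition", {
  expect_equal(nn_mse(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(nn_mse(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  expect_equal(nn_mse(c(1, 0), c(0, 1)), 1)
  expect_error(nn_mse(numeric(0), numeric(0)), "empty")
  expect_error(nn_mse(1, c(1, 0)))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(12)
  for (i in 1:5) {
    shape <- network_shape(sample(2:4, 1), sample(2:5, 1), 1)
    prob <- random_problem(n = 25, p = shape$n_input)
    v <- runif(network_dimension(shape), -1, 1)
    net <- decode_weights(v, shape)
    g <- nn_gradient(net, prob$X, prob$y)
    flat <- c(as.vector(t(g$W1)), g$b1, as.vector(t(g$W2)), g$b2)
    fd <- fd_gradient(v, shape, prob$X, prob$y)
    rel <- sqrt(sum((flat - fd)^2)) / max(sqrt(sum(fd^2)), 1e-12)
    expect_lt(rel, 1e-6)
  }
})

test_that("gradient descent lowers the training error monotonically at small steps", {
  prob <- random_problem(n = 60, p = 2, seed = 3)
  shape <- network_shape(2, 5, 1)
  net <- decode_weights(runif(network_dimension(shape), -1, 1), shape)
  lr <- 0.005
  errs <- nn_mse(nn_forward(net, prob$X), prob$y)
  for (e in 1:10) {
    g <- nn_gradient(net, prob$X, prob$y)
    net$W1 <- net$W1 - lr * g$W1; net$b1 <- net$b1 - lr * g$b1
    net$W2 <- net$W2 - lr * g$W2; net$b2 <- net$b2 - lr * g$b2
    errs <- c(errs, nn_mse(nn_forward(net, prob$X), prob$y))
  }
  expect_true(all(diff(errs) <= 0))
})

test_that("backprop training never worsens the starting network", {
  prob <- random_problem(n = 50, p = 3, seed = 21)
  shape <- network_shape(3, 5, 1)
  for (s in 1:5) {
    set.seed(s)
    net <- decode_weights(runif(network_dimension(shape), -1, 1), shape)
    init <- nn_mse(nn_forward(net, prob$X), prob$y)
    out <- backprop_train(net, prob$X, prob$y,
                          train_settings(max_epochs = 200))
    expect_lte(attr(out, "train_mse"), init)
    expect_equal(nn_mse(nn_forward(out, prob$X), prob$y),
                 attr(out, "train_mse"))
  }
})

test_that("training stops immediately when the goal is already met", {
  prob <- list(X = matrix(c(-5, 5)), y = c(0L, 1L))
  net <- network(matrix(20), 0, matrix(40), -20)  # near-perfect already
  init <- nn_mse(nn_forward(net, prob$X), prob$y)
  out <- backprop_train(net, prob$X, prob$y,
                        train_settings(goal = init + 1))
  expect_identical(attr(out, "epochs"), 0L)
  expect_equal(out$W1, net$W1)
  expect_equal(attr(out, "train_mse"), init)
})

test_that("training settings are validated", {
  expect_error(train_settings(learning_rate = 0))
  expect_error(train_settings(goal = -1))
  expect_error(train_settings(momentum = 1))
})

test_that("momentum accelerates descent without breaking the error contract", {
  prob <- random_problem(n = 80, p = 3, seed = 33)
  shape <- network_shape(3, 5, 1)
  set.seed(34)
  net <- decode_weights(runif(network_dimension(shape), -1, 1), shape)
  plain <- backprop_train(net, prob$X, prob$y,
                          train_settings(momentum = 0, max_epochs = 300,
                                         conv_tol = 0))
  accel <- backprop_train(net, prob$X, prob$y,
                          train_settings(momentum = 0.9, max_epochs = 300,
                                         conv_tol = 0))
  init <- nn_mse(nn_forward(net, prob$X), prob$y)
  expect_lte(attr(accel, "train_mse"), init)
  expect_lt(attr(accel, "train_mse"), attr(plain, "train_mse"))
})
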