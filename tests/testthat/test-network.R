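test_that("initialization is seed-reproducible with correct shapes", {
  n1 <- bp_network(6, 7, seed = 42)
  n2 <- bp_network(6, 7, seed = 42)
  n3 <- bp_network(6, 7, seed = 43)
  expect_identical(n1$iw, n2$iw)
  expect_identical(n1$lw, n2$lw)
  expect_false(isTRUE(all.equal(n1$iw, n3$iw)))
  expect_equal(dim(n1$iw), c(7, 6))
  expect_length(n1$lw, 7)
  expect_length(n1$b1, 7)
  expect_true(all(abs(c(n1$iw, n1$b1, n1$lw, n1$b2)) <= 0.5))
  expect_error(bp_network(0, 3), "input_size")
})

test_that("forward pass computes b2 + lw . tanh(iw x + b1)", {
  z <- bp_network(3, 2, seed = 1)
  z$iw[] <- 0; z$b1[] <- 0; z$lw[] <- 0; z$b2 <- 0
  expect_equal(nn_forward(z, c(1, 2, 3)), 0)
  z$lw <- c(5, -3); z$b2 <- 0.7        # tanh(0) = 0 so only b2 survives
  expect_equal(nn_forward(z, c(1, 2, 3)), 0.7)

  ## single hidden unit, hand-computed
  h <- bp_network(2, 1, seed = 1)
  h$iw[] <- c(0.5, -0.25); h$b1 <- 0.1; h$lw <- 2; h$b2 <- -1
  x <- c(0.8, 0.4)
  expect_equal(nn_forward(h, x), -1 + 2 * tanh(0.5 * 0.8 - 0.25 * 0.4 + 0.1))
  expect_error(nn_forward(h, c(1, 2, 3)), "dimension mismatch")
  ## matrix input vectorizes over rows
  xm <- rbind(x, c(0, 0))
  expect_equal(unname(nn_forward(h, xm))[1], nn_forward(h, x))
})

test_that("analytic gradients match central finite differences", {
  for (s in c(2, 9, 31)) {
    set.seed(s)
    net <- bp_network(4, 3, seed = s)
    x <- matrix(stats::runif(20, -1, 1), 5, 4)
    y <- stats::runif(5)
    ga <- aceqsar:::bp_gradient(net, x, y)
    gn <- numeric_gradient(net, x, y)
    expect_lt(max_rel_err(ga$iw, gn$iw), 1e-6)
    expect_lt(max_rel_err(ga$b1, gn$b1), 1e-6)
    expect_lt(max_rel_err(ga$lw, gn$lw), 1e-6)
    expect_lt(max_rel_err(ga$b2, gn$b2), 1e-6)
  }
})

test_that("a vanishing learning rate leaves the weights in place", {
  net <- bp_network(3, 2, seed = 5)
  x <- matrix(stats::runif(12), 4, 3)
  y <- stats::runif(4)
  fit <- bp_train(net, x, y, bp_control(learning_rate = 1e-300,
                                        max_epochs = 50, mse_goal = 1e-12))
  expect_equal(fit$network$iw, net$iw, tolerance = 1e-12)
  expect_equal(fit$network$lw, net$lw, tolerance = 1e-12)
})

test_that("a constant target is fitted to the goal through the output bias", {
  net <- bp_network(2, 2, seed = 3)
  x <- matrix(stats::runif(10), 5, 2)
  y <- rep(0.5, 5)
  fit <- bp_train(net, x, y, bp_control(learning_rate = 0.1, max_epochs = 2000,
                                        mse_goal = 1e-6))
  expect_true(fit$converged)
  expect_lt(fit$train_mse, 1e-6)
})

test_that("without momentum and with a small step the loss never increases", {
  for (s in c(4, 17)) {
    net <- bp_network(3, 4, seed = s)
    set.seed(s)
    x <- matrix(stats::runif(30), 10, 3)
    y <- stats::runif(10)
    fit <- bp_train(net, x, y, bp_control(learning_rate = 0.01, momentum = 0,
                                          max_epochs = 500, mse_goal = 1e-12))
    expect_true(all(diff(fit$loss_history) <= 1e-12))
  }
})

test_that("divergent training aborts with a diagnostic naming the epoch", {
  net <- bp_network(2, 2, seed = 1)
  x <- matrix(stats::runif(10), 5, 2)
  y <- stats::runif(5)
  expect_error(
    bp_train(net, x, y, bp_control(learning_rate = 1e150, max_epochs = 100)),
    "diverged.*epoch")
})

test_that("evaluation reports r and MSE with the documented conventions", {
  net <- bp_network(2, 1, seed = 1)
  x <- matrix(stats::runif(20), 10, 2)
  y <- nn_forward(net, x)
  ev <- bp_evaluate(net, x, y)
  expect_equal(ev$r, 1)
  expect_equal(ev$mse, 0)
  expect_equal(ev$n, 10)
  expect_equal(nrow(ev$predictions), 10)

  ## centered negated actuals anti-correlate exactly
  y2 <- -(y - mean(y)) + mean(y)
  ev2 <- bp_evaluate(net, x, y2)
  expect_equal(ev2$r, -1)

  ## Pearson r is invariant under a consistent affine rescaling
  sc <- fit_normalizer(ace_dipeptides())
  yr <- y * 0.9 + stats::rnorm(10, 0, 0.05)
  raw <- bp_evaluate(net, x, yr)
  den <- bp_evaluate(net, x, yr, scaler = sc)
  expect_equal(raw$r, den$r)
  expect_equal(raw$mse, den$mse)  # MSE stays on the normalized scale
  expect_equal(den$predictions$actual, denormalize_activity(sc, yr))

  expect_message(ev0 <- bp_evaluate(net, x, rep(0.3, 10)), "zero variance")
  expect_true(is.na(ev0$r))
})

test_that("random splits partition reproducibly", {
  d <- ace_dipeptides()
  s1 <- split_dataset(d, n_train = 39, seed = 7)
  s2 <- split_dataset(d, n_train = 39, seed = 7)
  expect_equal(nrow(s1$train), 39)
  expect_equal(nrow(s1$test), 19)
  expect_identical(s1$train_idx, s2$train_idx)
  joined <- rbind(as.data.frame(s1$train), as.data.frame(s1$test))
  expect_setequal(
    paste(joined$sequence, joined$activity),
    paste(d$sequence, d$activity))
  expect_error(split_dataset(d, n_train = 58), "n_train")
  expect_error(split_dataset(d, n_train = 0), "n_train")
})

test_that("model persistence round-trips weights and scaler exactly", {
  p <- quick_model()
  tf <- tempfile(fileext = ".json")
  save_model(p$network, tf, scaler = p$scaler)
  m <- load_model(tf)
  expect_equal(m$network$iw, p$network$iw, tolerance = 0)
  expect_equal(m$network$b1, p$network$b1, tolerance = 0)
  expect_equal(m$network$lw, p$network$lw, tolerance = 0)
  expect_equal(m$network$b2, p$network$b2, tolerance = 0)
  expect_equal(m$scaler$feature_min, p$scaler$feature_min, tolerance = 0)
  x <- encode_peptide("IW")
  xn <- suppressMessages(apply_normalizer(p$scaler, x))
  expect_identical(nn_forward(m$network, xn), nn_forward(p$network, xn))
})
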