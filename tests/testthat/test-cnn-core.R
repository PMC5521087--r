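# Unit tests of the network layers, loss, gradients and update rule.

test_that("sigmoid has its closed-form values and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  x <- seq(-10, 10, length.out = 41)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("conv_forward matches the brute-force oracle on small random inputs", {
  withr::with_seed(11, {
    for (case in 1:10) {
      side <- sample(4:16, 1)
      k <- sample.int(side - 1L, 1)
      n_in <- sample(1:3, 1)
      n_out <- sample(1:3, 1)
      maps <- array(rnorm(side^2 * n_in), c(side, side, n_in))
      W <- array(rnorm(k^2 * n_in * n_out), c(k, k, n_in, n_out))
      b <- rnorm(n_out)
      got <- conv_forward(maps, W, b)
      for (j in seq_len(n_out)) {
        acc <- matrix(b[j], side - k + 1L, side - k + 1L)
        for (i in seq_len(n_in)) {
          acc <- acc + oracle_conv(maps[, , i], matrix(W[, , i, j], k, k))
        }
        expect_lt(max(abs(got[, , j] - sigmoid(acc))), 1e-10)
      }
    }
  })
})

test_that("conv_forward honours sparse connection tables", {
  withr::with_seed(12, {
    maps <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    W <- array(rnorm(9 * 3 * 2), c(3, 3, 3, 2))
    got <- conv_forward(maps, W, c(0, 0), connections = list(2L, c(1L, 3L)))
    acc1 <- oracle_conv(maps[, , 2], W[, , 2, 1])
    acc2 <- oracle_conv(maps[, , 1], W[, , 1, 2]) + oracle_conv(maps[, , 3], W[, , 3, 2])
    expect_lt(max(abs(got[, , 1] - sigmoid(acc1))), 1e-10)
    expect_lt(max(abs(got[, , 2] - sigmoid(acc2))), 1e-10)
  })
})

test_that("conv_forward reproduces the published first-layer geometry", {
  # 272-pixel box with the derived 51-pixel kernel gives 222-pixel maps
  withr::with_seed(13, {
    maps <- array(rnorm(272^2), c(272, 272, 1))
    W <- array(rnorm(51^2), c(51, 51, 1, 1))
    out <- conv_forward(maps, W, 0)
    expect_identical(dim(out), c(222L, 222L, 1L))
  })
})

test_that("zero kernels and biases give the sigmoid midpoint everywhere", {
  maps <- array(rnorm(100), c(10, 10, 1))
  out <- conv_forward(maps, array(0, c(1, 1, 1, 1)), 0)
  expect_equal(as.vector(out), rep(0.5, 100))
})

test_that("conv_forward rejects inconsistent shapes", {
  maps <- array(rnorm(128), c(8, 8, 2))
  expect_error(conv_forward(maps, array(0, c(3, 3, 1, 2)), 0), "input maps")
  expect_error(conv_forward(maps, array(0, c(8, 8, 2, 1)), 0), "smaller")
  expect_error(conv_forward(maps, array(0, c(3, 3, 2, 1)), 0,
                            connections = list(5L)), "connections")
})

test_that("pool_forward is an exact block mean that conserves the global mean", {
  expect_equal(as.vector(pool_forward(matrix(c(1, 3, 2, 4), 2, 2), 2)), 2.5)
  const <- matrix(3.7, 6, 6)
  expect_equal(as.vector(pool_forward(const, 3)), rep(3.7, 4))
  withr::with_seed(14, {
    for (case in 1:8) {
      q <- sample(2:4, 1)
      side <- q * sample(2:4, 1)
      X <- matrix(rnorm(side^2), side, side)
      got <- pool_forward(X, q)[, , 1]
      expect_lt(max(abs(got - oracle_pool(X, q))), 1e-10)
      expect_equal(mean(got), mean(X))
    }
  })
  # published geometry: 222-pixel maps with 3x3 pooling give 74-pixel maps
  expect_identical(dim(pool_forward(array(0, c(222, 222, 1)), 3)),
                   c(74L, 74L, 1L))
  expect_error(pool_forward(matrix(0, 7, 7), 2), "divisible")
})

test_that("output_forward is an activated dot product", {
  maps <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  w <- rnorm(12)
  b <- 0.3
  expect_equal(output_forward(maps, w, b),
               sigmoid(sum(as.vector(maps) * w) + b))
  expect_equal(output_forward(maps, rep(0, 12), 0), 0.5)
  expect_error(output_forward(maps, rnorm(5), 0), "features")
})

test_that("network_forward is deterministic, bounded, and equals the composed layers", {
  st <- tiny_state()
  withr::with_seed(15, {
    for (case in 1:5) {
      box <- random_box()
      y <- network_forward(box, st)
      expect_identical(y, network_forward(box, st))
      expect_gt(y, 0); expect_lt(y, 1)
      expect_equal(y, compose_forward(box, st), tolerance = 1e-12)
    }
  })
  expect_error(network_forward(matrix(0, 9, 9), st), "8 x 8")
})

test_that("a zero output head scores every input 0.5", {
  st <- tiny_state()
  st$params$out$w[] <- 0
  st$params$out$b <- 0
  withr::with_seed(16, {
    expect_equal(network_forward(random_box(), st), 0.5)
    expect_equal(network_forward(random_box(), st), 0.5)
  })
})

test_that("the loss is half the mean squared residual", {
  expect_equal(cnn_loss(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(cnn_loss(0, 1), 0.5)
  expect_equal(cnn_loss(c(0, 0), c(1, 0)), 0.25)
  expect_error(cnn_loss(numeric(0), numeric(0)), "non-empty")
  expect_error(cnn_loss(c(0.5), c(1, 0)), "equal length")
})

test_that("backprop gradients match central finite differences everywhere", {
  st <- tiny_state(seed = 21)
  withr::with_seed(22, {
    boxes <- lapply(1:3, function(i) random_box())
  })
  targets <- c(1, 0, 1)
  g <- backprop_gradients(boxes, targets, st)
  arr <- cryopick:::as_box_array(boxes)
  loss_at <- function(s) cnn_loss(cryopick:::forward_scores(arr, s), targets)
  h <- 1e-5
  check <- function(get, set, ana) {
    n_checked <- 0L
    for (i in seq_along(get(st))) {
      sp <- set(st, i, get(st)[i] + h)
      sm <- set(st, i, get(st)[i] - h)
      num <- (loss_at(sp) - loss_at(sm)) / (2 * h)
      expect_lt(abs(num - ana[i]) / max(abs(num), abs(ana[i]), 1e-8), 1e-5)
      n_checked <- n_checked + 1L
    }
    n_checked
  }
  total <- 0L
  for (l in 1:3) {
    total <- total + check(
      function(s) s$params$conv[[l]]$W,
      function(s, i, v) { s$params$conv[[l]]$W[i] <- v; s },
      g$conv[[l]]$W)
    total <- total + check(
      function(s) s$params$conv[[l]]$b,
      function(s, i, v) { s$params$conv[[l]]$b[i] <- v; s },
      g$conv[[l]]$b)
  }
  total <- total + check(
    function(s) s$params$out$w,
    function(s, i, v) { s$params$out$w[i] <- v; s },
    g$out$w)
  total <- total + check(
    function(s) s$params$out$b,
    function(s, i, v) { s$params$out$b <- v; s },
    g$out$b)
  expect_identical(total, n_parameters(st$config))  # every parameter audited
})

test_that("zero residuals give zero gradients and duplication leaves means unchanged", {
  st <- tiny_state(seed = 23)
  withr::with_seed(24, boxes <- lapply(1:4, function(i) random_box()))
  scores <- cryopick:::forward_scores(cryopick:::as_box_array(boxes), st)
  g0 <- backprop_gradients(boxes, scores, st)  # targets equal the outputs
  expect_equal(max(abs(g0$conv[[1]]$W), abs(g0$out$w), abs(g0$out$b)), 0)

  targets <- c(1, 0, 0, 1)
  g1 <- backprop_gradients(boxes, targets, st)
  g2 <- backprop_gradients(c(boxes, boxes), c(targets, targets), st)
  for (l in 1:3) {
    expect_equal(g1$conv[[l]]$W, g2$conv[[l]]$W, tolerance = 1e-12)
    expect_equal(g1$conv[[l]]$b, g2$conv[[l]]$b, tolerance = 1e-12)
  }
  expect_equal(g1$out$w, g2$out$w, tolerance = 1e-12)
})

test_that("sgd_update is a linear step that can only descend for small eta", {
  st <- tiny_state(seed = 25)
  withr::with_seed(26, boxes <- lapply(1:4, function(i) random_box()))
  targets <- c(1, 0, 1, 0)
  g <- backprop_gradients(boxes, targets, st)

  zero <- rapply(g, function(x) x * 0, how = "replace")
  expect_equal(sgd_update(st, zero)$params, st$params)

  full <- sgd_update(st, g, eta = 1)
  half <- sgd_update(st, g, eta = 0.5)
  expect_equal(half$params$out$w - st$params$out$w,
               (full$params$out$w - st$params$out$w) / 2)

  arr <- cryopick:::as_box_array(boxes)
  loss0 <- cnn_loss(cryopick:::forward_scores(arr, st), targets)
  st1 <- sgd_update(st, g, eta = 1e-2)
  loss1 <- cnn_loss(cryopick:::forward_scores(arr, st1), targets)
  expect_lte(loss1, loss0)

  expect_error(sgd_update(st, g, eta = 0), "positive")
  expect_error(sgd_update(st, g, eta = -1), "positive")
})

test_that("initialization is seeded, uniform on [0,1), and shape-consistent", {
  cfg <- preset_config("klh")
  a <- init_network(cfg, seed = 31)
  b <- init_network(cfg, seed = 31)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, init_network(cfg, seed = 32)$params))

  all_vals <- c(unlist(lapply(a$params$conv, function(l) c(l$W, l$b))),
                a$params$out$w, a$params$out$b)
  expect_true(all(all_vals >= 0 & all_vals < 1))

  # independent parameter count from the printed schedule:
  # kernels 51,21,10; maps 1->6->12->12; head 12*9^2+1
  expected <- (51^2 * 1 * 6 + 6) + (21^2 * 6 * 12 + 12) + (10^2 * 12 * 12 + 12) +
    (12 * 9^2 + 1)
  expect_identical(length(all_vals), as.integer(expected))
  expect_identical(n_parameters(cfg), as.integer(expected))
  expect_identical(length(a$params$out$w), 972L)
})

test_that("symmetric initialization and shared-layer bias options behave", {
  cfg <- tiny_config(init = "symmetric", bias = "layer")
  st <- init_network(cfg, seed = 33)
  for (l in 1:3) {
    expect_equal(length(unique(st$params$conv[[l]]$b)), 1L)
    a <- 1 / sqrt(cfg$kernel_sides[l]^2 * c(1, 2, 2)[l])
    expect_true(all(abs(st$params$conv[[l]]$W) <= a))
  }
  # shared-bias gradient accumulates over the layer's maps
  withr::with_seed(34, boxes <- lapply(1:2, function(i) random_box()))
  g <- backprop_gradients(boxes, c(1, 0), st)
  for (l in 1:3) expect_equal(length(unique(g$conv[[l]]$b)), 1L)
})
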