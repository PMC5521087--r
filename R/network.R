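# The feed-forward network and its exact gradients.
#
# Layer operations are exposed individually (conv_forward, pool_forward,
# output_forward) so the composition can be audited piecewise; the full
# forward pass, the batched gradient computation and the raster scan run in
# compiled code with identical arithmetic.

#' Logistic sigmoid activation
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the activation applied after every
#' convolution and at the scoring output.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(activation) {
  switch(activation,
         sigmoid = sigmoid,
         relu = function(x) pmax(x, 0),
         stop("unknown activation: ", activation, call. = FALSE))
}

#' Initialize the network parameters
#'
#' Draws every weight and bias independently from the distribution named in
#' the configuration: uniform on `[0, 1)` (the default), or symmetric uniform
#' on `[-1/sqrt(fan-in), 1/sqrt(fan-in)]`. Fully seeded: the same seed yields
#' bit-identical parameters.
#'
#' @param config A [network_config()] object.
#' @param seed Integer RNG seed.
#' @return A `cnn_state` holding the configuration and all parameters.
#' @export
init_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  lay <- conv_layout(config)
  draw <- function(n, fan_in) {
    if (config$init == "uniform") return(runif(n))
    a <- 1 / sqrt(fan_in)
    runif(n, -a, a)
  }
  params <- withr::with_seed(as.integer(seed), {
    conv <- vector("list", 3L)
    for (l in 1:3) {
      k <- lay$kernel[l]
      fan <- k^2 * lay$n_in[l]
      W <- array(draw(k^2 * lay$n_in[l] * lay$n_out[l], fan),
                 c(k, k, lay$n_in[l], lay$n_out[l]))
      b <- if (config$bias == "map") draw(lay$n_out[l], fan) else
        rep(draw(1L, fan), lay$n_out[l])
      conv[[l]] <- list(W = W, b = b)
    }
    out <- list(w = draw(lay$n_features, lay$n_features),
                b = draw(1L, lay$n_features))
    list(conv = conv, out = out)
  })
  structure(list(config = config, params = params, rng_seed = as.integer(seed)),
            class = "cnn_state")
}

#' @export
print.cnn_state <- function(x, ...) {
  cat("<cnn_state> parameters for:\n")
  print(x$config)
  invisible(x)
}

#' Convolutional layer forward pass
#'
#' Valid (unit-stride, no padding) shared-kernel cross-correlation: output map
#' `j` is `activation(sum over connected inputs i of X_i * W[, , i, j] + b[j])`.
#' The output side is `input side - kernel side + 1`.
#'
#' @param maps Input feature maps as a (side, side, n_in) array or a single
#'   matrix.
#' @param weights Kernels as a (k, k, n_in, n_out) array.
#' @param bias Numeric vector of length n_out (recycled if length 1).
#' @param activation `"sigmoid"` (default) or `"relu"`.
#' @param connections Optional list, one element per output map, of input-map
#'   indices that feed it; default full connectivity.
#' @return A (side - k + 1, side - k + 1, n_out) array.
#' @export
conv_forward <- function(maps, weights, bias, activation = "sigmoid",
                         connections = NULL) {
  maps <- as_box_array(maps)
  d <- dim(weights)
  if (length(d) != 4L || d[1L] != d[2L]) {
    stop("weights must be a (k, k, n_in, n_out) array", call. = FALSE)
  }
  k <- d[1L]; n_in <- d[3L]; n_out <- d[4L]
  if (dim(maps)[3L] != n_in) {
    stop("kernel array expects ", n_in, " input maps, got ", dim(maps)[3L],
         call. = FALSE)
  }
  if (k >= dim(maps)[1L]) {
    stop("kernel side must be smaller than the input map side", call. = FALSE)
  }
  bias <- rep_len(bias, n_out)
  if (is.null(connections)) connections <- rep(list(seq_len(n_in)), n_out)
  if (length(connections) != n_out ||
      any(!vapply(connections, function(s) length(s) > 0L && all(s >= 1L & s <= n_in),
                  logical(1L)))) {
    stop("connections must give a non-empty valid input subset per output map",
         call. = FALSE)
  }
  f <- act_fun(activation)
  side <- dim(maps)[1L] - k + 1L
  out <- array(0, c(side, side, n_out))
  for (j in seq_len(n_out)) {
    acc <- matrix(bias[j], side, side)
    for (i in connections[[j]]) {
      acc <- acc + cpp_conv_valid(matrix(maps[, , i], dim(maps)[1L]),
                                  matrix(weights[, , i, j], k, k))
    }
    out[, , j] <- f(acc)
  }
  out
}

#' Average subsampling layer forward pass
#'
#' Non-overlapping block means over `pool[1] x pool[2]` tiles: a pure average
#' with no learnable parameters and no activation. Input sides must divide
#' exactly by the pool size.
#'
#' @param maps Feature maps as a (side, side, n) array or a matrix.
#' @param pool Pool size, a single integer or `c(rows, cols)`.
#' @return The pooled (side/pool, side/pool, n) array.
#' @export
pool_forward <- function(maps, pool) {
  maps <- as_box_array(maps)
  pool <- as.integer(rep_len(pool, 2L))
  if (any(pool < 1L)) stop("pool size must be at least 1", call. = FALSE)
  if (dim(maps)[1L] %% pool[1L] != 0L || dim(maps)[2L] %% pool[2L] != 0L) {
    stop("map side (", dim(maps)[1L], "x", dim(maps)[2L],
         ") is not divisible by the pool size", call. = FALSE)
  }
  out <- array(0, c(dim(maps)[1L] %/% pool[1L], dim(maps)[2L] %/% pool[2L],
                    dim(maps)[3L]))
  for (i in seq_len(dim(maps)[3L])) {
    out[, , i] <- cpp_pool_avg(matrix(maps[, , i], dim(maps)[1L]),
                               pool[1L], pool[2L])
  }
  out
}

#' Fully connected output layer
#'
#' Flattens the final feature maps (column-major) and returns
#' `activation(dot(features, weights) + bias)`, the scalar particle score.
#'
#' @param maps Final subsampling-layer maps, (side, side, n) array.
#' @param weights Numeric vector matching the flattened feature count.
#' @param bias Scalar bias.
#' @param activation Output activation; `"sigmoid"` keeps scores in (0, 1).
#' @return A single numeric score.
#' @export
output_forward <- function(maps, weights, bias, activation = "sigmoid") {
  maps <- as_box_array(maps)
  flat <- as.vector(maps)
  if (length(flat) != length(weights)) {
    stop("output layer expects ", length(weights), " features, got ",
         length(flat), call. = FALSE)
  }
  act_fun(activation)(sum(flat * weights) + bias)
}

# batch forward through the compiled core; boxes as (side, side, n) array,
# already normalized as the configuration requires
forward_scores <- function(arr, state) {
  cpp_forward_batch(arr, state$params, state$config$box_side,
                    as.integer(state$config$pool_sizes), act_code(state$config))
}

maybe_standardize_boxes <- function(arr, config) {
  if (config$normalize != "box") return(arr)
  for (i in seq_len(dim(arr)[3L])) arr[, , i] <- standardize_grid(arr[, , i])
  arr
}

#' Full forward pass of the eight-layer network
#'
#' Composes C1 -> S2 -> C3 -> S4 -> C5 -> S6 -> output on a single box.
#' Deterministic given the state; with sigmoid output the score is always in
#' the open interval (0, 1).
#'
#' @param box Square numeric matrix with side `config$box_side`.
#' @param state A `cnn_state` from [init_network()] or training.
#' @return The scalar score.
#' @export
network_forward <- function(box, state) {
  state <- as_cnn_state(state)
  assert_grid(box, "box")
  side <- state$config$box_side
  if (nrow(box) != side || ncol(box) != side) {
    stop("box must be ", side, " x ", side, " for this configuration",
         call. = FALSE)
  }
  arr <- maybe_standardize_boxes(array(box, c(side, side, 1L)), state$config)
  forward_scores(arr, state)[1L]
}

#' Half mean squared error loss
#'
#' `E_N = 1/(2N) * sum_n (t_n - y_n)^2`, the squared-error objective the
#' network is trained to minimize.
#'
#' @param outputs Numeric vector of network scores.
#' @param targets Numeric vector of 0/1 labels of the same length.
#' @return Non-negative scalar.
#' @export
cnn_loss <- function(outputs, targets) {
  if (length(outputs) == 0L || length(outputs) != length(targets)) {
    stop("outputs and targets must be non-empty vectors of equal length",
         call. = FALSE)
  }
  mean((targets - outputs)^2) / 2
}

#' Exact back-propagated gradients of the loss
#'
#' Returns the derivative of [cnn_loss()] over the batch with respect to every
#' weight and bias, computed by explicit reverse-mode back-propagation:
#' sigmoid derivative `y(1-y)` at each unit, kernel gradients summed over all
#' spatial applications of the shared weights, and pooling gradients spread
#' uniformly with factor `1/(MN)`.
#'
#' @param boxes Training boxes as a list of matrices or a (side, side, n)
#'   array.
#' @param targets 0/1 labels, one per box.
#' @param state A `cnn_state`.
#' @return A gradient set shaped exactly like `state$params`, with the batch
#'   scores attached as attribute `"scores"`.
#' @export
backprop_gradients <- function(boxes, targets, state) {
  state <- as_cnn_state(state)
  arr <- as_box_array(boxes)
  side <- state$config$box_side
  if (dim(arr)[1L] != side || dim(arr)[2L] != side) {
    stop("boxes must match the configured box side ", side, call. = FALSE)
  }
  if (length(targets) != dim(arr)[3L]) {
    stop("one target per box required", call. = FALSE)
  }
  arr <- maybe_standardize_boxes(arr, state$config)
  g <- cpp_backprop_batch(arr, as.numeric(targets), state$params, side,
                          as.integer(state$config$pool_sizes),
                          act_code(state$config))
  scores <- g$scores
  g$scores <- NULL
  # a layer-shared bias accumulates the gradient of all its maps
  if (state$config$bias == "layer") {
    for (l in 1:3) g$conv[[l]]$b <- rep(sum(g$conv[[l]]$b), length(g$conv[[l]]$b))
  }
  attr(g, "scores") <- scores
  g
}

#' Gradient-descent parameter update
#'
#' `omega <- omega - eta * gradient`, where the gradient is already the batch
#' mean as returned by [backprop_gradients()]. The learning rate defaults to
#' 1, the value used throughout this method.
#'
#' @param state A `cnn_state`.
#' @param gradients Gradient set from [backprop_gradients()].
#' @param eta Positive learning rate.
#' @return The updated `cnn_state`.
#' @export
sgd_update <- function(state, gradients, eta = 1) {
  state <- as_cnn_state(state)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    stop("eta must be a positive number", call. = FALSE)
  }
  for (l in 1:3) {
    state$params$conv[[l]]$W <- state$params$conv[[l]]$W - eta * gradients$conv[[l]]$W
    state$params$conv[[l]]$b <- state$params$conv[[l]]$b - eta * gradients$conv[[l]]$b
  }
  state$params$out$w <- state$params$out$w - eta * gradients$out$w
  state$params$out$b <- state$params$out$b - eta * gradients$out$b
  state
}

as_cnn_state <- function(x) {
  if (inherits(x, "cnn_fit")) return(x$state)
  if (inherits(x, "cnn_state")) return(x)
  stop("expected a cnn_state or cnn_fit object", call. = FALSE)
}
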