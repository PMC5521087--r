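# Layer schedule of the eight-layer network.
#
# The architecture is fixed in shape: input box -> C1 -> S2 -> C3 -> S4 ->
# C5 -> S6 -> fully connected scoring output, where C layers are valid
# unit-stride convolutions followed by the activation and S layers are
# non-overlapping average pools.  A configuration is specified, as in the
# published hyper-parameter tables for this architecture, by the box side and
# the six per-layer map sides; kernel and pool sizes are forced by the shape
# arithmetic (kernel = in - out + 1 for a convolution, pool = in / out for a
# subsampling layer) and validated here.

#' Configure the eight-layer picking network
#'
#' Builds and validates the layer schedule from the feature-map sides, the
#' way the architecture is conventionally tabulated.  Kernel sides are derived
#' as `in - out + 1` (valid convolution, unit stride) and pool sizes as
#' `in / out`, which must divide exactly.
#'
#' @param box_side Side of the square input box, in pixels.
#' @param map_sides Integer vector of the six feature-map sides for layers
#'   C1, S2, C3, S4, C5, S6.
#' @param n_maps Integer vector of the six feature-map counts; pooling layers
#'   must repeat the count of the convolution they follow. Default
#'   `c(6, 6, 12, 12, 12, 12)` as in the published schedules.
#' @param activation Hidden-layer activation, `"sigmoid"` (default) or
#'   `"relu"`. The scoring output is always sigmoid so scores stay in (0, 1).
#' @param bias `"map"` (default) for one bias per output feature map, or
#'   `"layer"` for a single bias shared by all maps of a layer.
#' @param init `"uniform"` (default) to initialize every weight and bias
#'   uniformly in `[0, 1)`, or `"symmetric"` for uniform in
#'   `[-1/sqrt(fan-in), 1/sqrt(fan-in)]`.
#' @param normalize `"none"` (default) or `"box"`; with `"box"` every input
#'   box is standardized to zero mean and unit variance before entering the
#'   network. The recommended pipeline standardizes whole micrographs instead
#'   (see [standardize_grid()]), which keeps the raster scan translation
#'   shareable.
#' @return An object of class `cnn_config`.
#' @export
#' @examples
#' cfg <- network_config(272, c(222, 74, 54, 27, 18, 9))
#' cfg$kernel_sides # 51 21 10
#' cfg$pool_sizes   # 3 2 2
network_config <- function(box_side,
                           map_sides,
                           n_maps = c(6L, 6L, 12L, 12L, 12L, 12L),
                           activation = c("sigmoid", "relu"),
                           bias = c("map", "layer"),
                           init = c("uniform", "symmetric"),
                           normalize = c("none", "box")) {
  activation <- match.arg(activation)
  bias <- match.arg(bias)
  init <- match.arg(init)
  normalize <- match.arg(normalize)
  box_side <- as.integer(box_side)
  map_sides <- as.integer(map_sides)
  n_maps <- as.integer(n_maps)
  if (length(map_sides) != 6L || length(n_maps) != 6L) {
    stop("map_sides and n_maps must each list the six layers C1,S2,C3,S4,C5,S6",
         call. = FALSE)
  }
  if (any(map_sides < 1L) || any(n_maps < 1L) || box_side < 2L) {
    stop("invalid layer schedule: sides and map counts must be positive",
         call. = FALSE)
  }
  if (n_maps[2L] != n_maps[1L] || n_maps[4L] != n_maps[3L] ||
      n_maps[6L] != n_maps[5L]) {
    stop("a subsampling layer must keep the map count of the preceding ",
         "convolutional layer", call. = FALSE)
  }
  conv_in <- c(box_side, map_sides[2L], map_sides[4L])
  conv_out <- map_sides[c(1L, 3L, 5L)]
  kernel_sides <- conv_in - conv_out + 1L
  if (any(kernel_sides < 1L) || any(kernel_sides >= conv_in)) {
    stop("inconsistent schedule: each convolution kernel must have side in ",
         "[1, input side)", call. = FALSE)
  }
  pool_in <- map_sides[c(1L, 3L, 5L)]
  pool_out <- map_sides[c(2L, 4L, 6L)]
  if (any(pool_in %% pool_out != 0L)) {
    stop("inconsistent schedule: each pooled side must divide the side of ",
         "the preceding convolutional layer exactly", call. = FALSE)
  }
  pool_sizes <- pool_in %/% pool_out
  structure(
    list(box_side = box_side, map_sides = map_sides, n_maps = n_maps,
         kernel_sides = kernel_sides, pool_sizes = pool_sizes,
         activation = activation, bias = bias, init = init,
         normalize = normalize),
    class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat("<cnn_config> eight-layer picking network\n")
  cat(sprintf("  input box: %d x %d\n", x$box_side, x$box_side))
  lab <- c("C1", "S2", "C3", "S4", "C5", "S6")
  det <- character(6L)
  det[c(1, 3, 5)] <- sprintf("kernel %d", x$kernel_sides)
  det[c(2, 4, 6)] <- sprintf("pool %d", x$pool_sizes)
  for (i in 1:6) {
    cat(sprintf("  %s: %d@%dx%d (%s)\n", lab[i], x$n_maps[i], x$map_sides[i],
                x$map_sides[i], det[i]))
  }
  cat(sprintf("  output: fully connected, %d features -> 1 score\n",
              x$n_maps[6L] * x$map_sides[6L]^2))
  cat(sprintf("  activation %s, bias per %s, init %s, %d parameters\n",
              x$activation, x$bias, x$init, n_parameters(x)))
  invisible(x)
}

#' Published and desk-scale layer schedules
#'
#' The four benchmark schedules used with this architecture (KLH at box 272,
#' the 19S regulatory particle at 160, the 26S proteasome at 150, the
#' inflammasome at 112) plus `"synthetic64"`, a reduced schedule with the
#' same shape grammar for 64-pixel boxes, used by the synthetic-data
#' experiments in this package.
#'
#' @param name One of `"klh"`, `"proteasome19s"`, `"proteasome26s"`,
#'   `"inflammasome"`, `"synthetic64"`.
#' @param ... Passed on to [network_config()] to override defaults.
#' @return A `cnn_config`.
#' @export
preset_config <- function(name = c("klh", "proteasome19s", "proteasome26s",
                                   "inflammasome", "synthetic64"), ...) {
  name <- match.arg(name)
  sched <- switch(name,
    klh           = list(272L, c(222L, 74L, 54L, 27L, 18L, 9L)),
    proteasome19s = list(160L, c(141L, 47L, 38L, 19L, 16L, 8L)),
    proteasome26s = list(150L, c(120L, 60L, 46L, 23L, 14L, 7L)),
    inflammasome  = list(112L, c(98L, 49L, 40L, 20L, 14L, 7L)),
    synthetic64   = list(64L, c(56L, 28L, 24L, 12L, 9L, 3L)))
  defaults <- list(box_side = sched[[1L]], map_sides = sched[[2L]])
  extra <- list(...)
  # the desk-scale preset trains from symmetric initialization; all-positive
  # uniform[0,1) starts a three-sigmoid-layer net deep in saturation
  if (name == "synthetic64" && is.null(extra$init)) extra$init <- "symmetric"
  do.call(network_config, c(defaults, extra))
}

#' Count the learnable parameters of a configuration
#'
#' @param config A `cnn_config`.
#' @return Integer number of weights and biases.
#' @export
n_parameters <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  n_in <- c(1L, config$n_maps[2L], config$n_maps[4L])
  n_out <- config$n_maps[c(1L, 3L, 5L)]
  nb <- if (config$bias == "map") n_out else rep(1L, 3L)
  conv <- sum(config$kernel_sides^2 * n_in * n_out + nb)
  out <- config$n_maps[6L] * config$map_sides[6L]^2 + 1L
  as.integer(conv + out)
}

# layer-wise shapes used by the compiled core
conv_layout <- function(config) {
  list(n_in = c(1L, config$n_maps[2L], config$n_maps[4L]),
       n_out = config$n_maps[c(1L, 3L, 5L)],
       kernel = config$kernel_sides,
       pool = config$pool_sizes,
       n_features = config$n_maps[6L] * config$map_sides[6L]^2)
}

act_code <- function(config) if (config$activation == "relu") 1L else 0L
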