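# Recognition: raster scanning, rotation-averaged scoring, and candidate
# selection by threshold, local maximum and pixel-standard-deviation rules.

score_box_batch <- function(boxes, state, rotation_average = TRUE) {
  arr <- maybe_standardize_boxes(as_box_array(boxes), state$config)
  n <- dim(arr)[3L]
  if (!rotation_average) return(forward_scores(arr, state))
  side <- dim(arr)[1L]
  big <- array(0, c(side, side, 4L * n))
  for (i in seq_len(n)) {
    b <- arr[, , i]
    for (r in 0:3) {
      big[, , (i - 1L) * 4L + r + 1L] <- if (r == 0L) b else rotate_grid(b, r)
    }
  }
  s <- forward_scores(big, state)
  colMeans(matrix(s, nrow = 4L))
}

#' Rotation-averaged particle score of a box
#'
#' Scores the box and its three quarter-turn copies with the network and
#' returns the mean of the four outputs. The score is exactly invariant under
#' quarter-turn rotation of the input, since the four-fold orbit is the same
#' set of images.
#'
#' @param box Square numeric matrix with the configured box side.
#' @param state A `cnn_state` or `cnn_fit`.
#' @return Scalar score in (0, 1).
#' @export
score_box <- function(box, state) {
  state <- as_cnn_state(state)
  assert_grid(box, "box")
  if (nrow(box) != state$config$box_side || ncol(box) != state$config$box_side) {
    stop("box must be ", state$config$box_side, " pixels square", call. = FALSE)
  }
  score_box_batch(list(box), state)[1L]
}

#' Raster-scan a micrograph with the trained network
#'
#' Evaluates the (by default rotation-averaged) particle score at every
#' stride-spaced box position, starting at the top-left corner; boxes are
#' placed only fully inside the micrograph. Returns a `score_map` whose grid
#' has `floor((side - box_side) / stride) + 1` positions per axis.
#'
#' When the stride divides `micrograph side - box side` on both axes, the
#' scan runs fully convolutionally: shared layers are computed once per
#' pooling-alignment class, which is arithmetically identical to scoring each
#' box independently but orders of magnitude faster. Otherwise a per-box
#' fallback is used.
#'
#' Note: the micrograph is scanned as given; standardize it first (or use
#' [pick_particles()], which does) so that scanning matches how the training
#' boxes were normalized.
#'
#' @param micrograph Numeric matrix, larger than the box on both axes.
#' @param state A `cnn_state` or `cnn_fit`.
#' @param stride Pixels between adjacent raster positions (default 4).
#' @param rotation_average Average scores over the four quarter-turn copies of
#'   every box (default `TRUE`, as in recognition).
#' @return A `score_map` object.
#' @export
scan_micrograph <- function(micrograph, state, stride = 4L,
                            rotation_average = TRUE) {
  state <- as_cnn_state(state)
  assert_grid(micrograph, "micrograph")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) {
    stop("stride must be a positive integer", call. = FALSE)
  }
  b <- state$config$box_side
  H <- nrow(micrograph); W <- ncol(micrograph)
  if (H <= b || W <= b) {
    stop("micrograph must be larger than the ", b, "-pixel box on both axes",
         call. = FALSE)
  }
  pools <- as.integer(state$config$pool_sizes)
  acode <- act_code(state$config)
  per_box_norm <- state$config$normalize == "box"
  shareable <- !per_box_norm &&
    (!rotation_average || ((H - b) %% stride == 0L && (W - b) %% stride == 0L))

  scores <- if (shareable && !rotation_average) {
    cpp_scan_shared(micrograph, state$params, b, pools, acode, stride)
  } else if (shareable) {
    scan_shared_rotavg(micrograph, state, stride)
  } else {
    if (per_box_norm) {
      scan_naive_normalized(micrograph, state, stride, rotation_average)
    } else {
      cpp_scan_naive(micrograph, state$params, b, pools, acode, stride,
                     rotation_average)
    }
  }
  structure(list(scores = scores, stride = stride, box_side = b,
                 origin = c(0L, 0L), micrograph_dim = c(H, W),
                 rotation_average = rotation_average),
            class = "score_map")
}

# rotation-averaged shared scan: scan the four rotations of the micrograph
# and map each score grid back onto the original position grid
scan_shared_rotavg <- function(micrograph, state, stride) {
  b <- state$config$box_side
  pools <- as.integer(state$config$pool_sizes)
  acode <- act_code(state$config)
  H <- nrow(micrograph); W <- ncol(micrograph)
  ny <- (H - b) %/% stride + 1L
  nx <- (W - b) %/% stride + 1L
  # grid indices (1-based) of every position, updated through the rotations
  iy <- rep(seq_len(ny), times = nx)
  ix <- rep(seq_len(nx), each = ny)
  acc <- matrix(0, ny, nx)
  m <- micrograph
  h <- H; w <- W
  for (r in 0:3) {
    s <- cpp_scan_shared(m, state$params, b, pools, acode, stride)
    acc <- acc + matrix(s[cbind(iy, ix)], ny, nx)
    if (r == 3L) break
    # a clockwise quarter turn maps box corner (x, y) to (h - b - y, x)
    new_iy <- ix
    new_ix <- (h - b) %/% stride + 2L - iy
    iy <- new_iy; ix <- new_ix
    m <- rotate_grid(m, 1L)
    tmp <- h; h <- w; w <- tmp
  }
  acc / 4
}

scan_naive_normalized <- function(micrograph, state, stride, rotation_average) {
  b <- state$config$box_side
  ny <- (nrow(micrograph) - b) %/% stride + 1L
  nx <- (ncol(micrograph) - b) %/% stride + 1L
  out <- matrix(0, ny, nx)
  for (iy in seq_len(ny)) {
    boxes <- lapply(seq_len(nx), function(ix) {
      micrograph[(iy - 1L) * stride + seq_len(b), (ix - 1L) * stride + seq_len(b)]
    })
    out[iy, ] <- score_box_batch(boxes, state, rotation_average)
  }
  out
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %d x %d positions (stride %d, box %d) over a %d x %d micrograph\n",
              nrow(x$scores), ncol(x$scores), x$stride, x$box_side,
              x$micrograph_dim[1L], x$micrograph_dim[2L]))
  cat(sprintf("  scores in [%.4f, %.4f]%s\n", min(x$scores), max(x$scores),
              if (x$rotation_average) ", rotation averaged" else ""))
  invisible(x)
}

#' Select candidate particles from a score map
#'
#' Keeps the raster positions whose score is at or above the threshold and is
#' a strict maximum within the non-maximum-suppression radius (Chebyshev
#' distance in micrograph pixels); score ties are broken by raster order, the
#' top-left position winning. Candidates are returned sorted by descending
#' score.
#'
#' @param score_map A [scan_micrograph()] result.
#' @param threshold Score threshold in (0, 1).
#' @param nms_radius Suppression radius in pixels; default half the box side.
#' @param micrograph Optional source micrograph; when supplied, each
#'   candidate's box pixel standard deviation is attached as `pixel_std`.
#' @return Tibble with columns `x`, `y` (0-based corner coordinates), `score`
#'   and optionally `pixel_std`.
#' @export
find_candidates <- function(score_map, threshold, nms_radius = NULL,
                            micrograph = NULL) {
  stopifnot(inherits(score_map, "score_map"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(nms_radius)) nms_radius <- score_map$box_side / 2
  if (nms_radius <= 0) stop("nms_radius must be positive", call. = FALSE)
  rad_cells <- as.integer(floor(nms_radius / score_map$stride))
  keep <- cpp_local_maxima(score_map$scores, rad_cells) &
    score_map$scores >= threshold
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble(x = as.integer((idx[, 2L] - 1L) * score_map$stride +
                                 score_map$origin[2L]),
                y = as.integer((idx[, 1L] - 1L) * score_map$stride +
                                 score_map$origin[1L]),
                score = unname(score_map$scores[idx]))
  if (!is.null(micrograph)) {
    assert_grid(micrograph, "micrograph")
    b <- score_map$box_side
    out$pixel_std <- vapply(seq_len(nrow(out)), function(i) {
      stats::sd(micrograph[out$y[i] + seq_len(b), out$x[i] + seq_len(b)])
    }, numeric(1L))
  }
  dplyr::arrange(out, dplyr::desc(.data$score), .data$y, .data$x)
}

#' Filter candidates by pixel standard deviation
#'
#' Contaminated or carbon-rich areas give boxes whose pixel standard
#' deviation is unusually high or low, so candidates are kept only within a
#' narrow band: either `mean +/- k * sd` of the `pixel_std` values over the
#' micrograph's own candidates (the default), or an absolute `range = c(lo,
#' hi)`. With fewer than two candidates the relative band is undefined and
#' the filter is a no-op.
#'
#' @param candidates Candidate tibble carrying a `pixel_std` column.
#' @param k Width of the relative band in candidate-std standard deviations.
#' @param range Optional absolute `c(lo, hi)` band overriding the relative
#'   rule.
#' @return The filtered candidate tibble.
#' @export
filter_by_std <- function(candidates, k = 2, range = NULL) {
  stopifnot(is.data.frame(candidates))
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1L] <= range[2L])
    return(candidates[candidates$pixel_std >= range[1L] &
                      candidates$pixel_std <= range[2L], , drop = FALSE])
  }
  if (!is.numeric(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(candidates) < 2L) return(candidates)
  if (!"pixel_std" %in% names(candidates)) {
    stop("candidates carry no pixel_std column", call. = FALSE)
  }
  mu <- mean(candidates$pixel_std)
  sig <- stats::sd(candidates$pixel_std)
  if (sig == 0) return(candidates)
  keep <- abs(candidates$pixel_std - mu) <= k * sig
  candidates[keep, , drop = FALSE]
}

#' Pick particles from a micrograph
#'
#' The full recognition pipeline: standardize the micrograph (by default),
#' raster-scan it with rotation-averaged scoring, keep thresholded local
#' maxima, and apply the pixel-standard-deviation filter. Deterministic given
#' its inputs.
#'
#' @param micrograph Numeric matrix.
#' @param state A `cnn_state` or `cnn_fit`.
#' @param threshold Score threshold, typically the F2-selected value from
#'   [select_threshold()].
#' @param stride Raster stride in pixels (default 4).
#' @param nms_radius Suppression radius in pixels; default half the box side.
#' @param std_k Width of the relative pixel-std band (default 2).
#' @param std_range Optional absolute pixel-std band `c(lo, hi)`.
#' @param normalize Standardize the micrograph to zero mean, unit variance
#'   before scanning (default `TRUE`; disable if the micrograph is already
#'   normalized).
#' @param rotation_average Average scores over the four box rotations.
#' @return Candidate tibble (`x`, `y`, `score`, `pixel_std`) with the box
#'   side attached as attribute `box_side`.
#' @export
pick_particles <- function(micrograph, state, threshold, stride = 4L,
                           nms_radius = NULL, std_k = 2, std_range = NULL,
                           normalize = TRUE, rotation_average = TRUE) {
  state <- as_cnn_state(state)
  assert_grid(micrograph, "micrograph")
  if (normalize && state$config$normalize != "box") {
    micrograph <- standardize_grid(micrograph)
  }
  sm <- scan_micrograph(micrograph, state, stride = stride,
                        rotation_average = rotation_average)
  cand <- find_candidates(sm, threshold, nms_radius = nms_radius,
                          micrograph = micrograph)
  cand <- filter_by_std(cand, k = std_k, range = std_range)
  attr(cand, "box_side") <- state$config$box_side
  cand
}
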