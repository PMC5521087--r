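# Plain-matrix image utilities.
#
# An image grid is an ordinary numeric matrix indexed [row, col] with the
# origin at the top-left corner, rows running downward (y) and columns
# rightward (x).  Pixel coordinates used throughout the package are 0-based,
# so the pixel at matrix position [1, 1] has coordinates (x = 0, y = 0).

assert_grid <- function(m, what = "image") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop(what, " must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(m)
}

#' Rotate an image grid by quarter turns
#'
#' Exact lossless rotation by multiples of 90 degrees (clockwise for positive
#' `k`).  Used for training-set augmentation and rotation-averaged scoring,
#' where the four-fold orbit of a square box is needed without interpolation.
#'
#' @param m Numeric matrix.
#' @param k Integer number of clockwise quarter turns (any integer; only
#'   `k %% 4` matters).
#' @return The rotated matrix.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3)
#' rotate_grid(m, 4) == m
rotate_grid <- function(m, k = 1L) {
  assert_grid(m)
  k <- as.integer(k) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1L, , drop = FALSE])
  m
}

#' Standardize an image grid to zero mean and unit variance
#'
#' @param m Numeric matrix.
#' @return `(m - mean(m)) / sd(m)`; if the grid is constant the centred grid
#'   is returned unscaled.
#' @export
standardize_grid <- function(m) {
  assert_grid(m)
  s <- stats::sd(m)
  m <- m - mean(m)
  if (s > 0) m <- m / s
  m
}

#' Bin a micrograph by block averaging
#'
#' Averages non-overlapping `factor` x `factor` tiles, the usual way large
#' micrographs are reduced (e.g. 7420 x 7676 binned 4x gives 1855 x 1919).
#' Trailing rows and columns that do not fill a complete tile are cropped.
#'
#' @param micrograph Numeric matrix.
#' @param factor Integer binning factor, at least 1.
#' @return The binned matrix of dimension `floor(dim(micrograph) / factor)`.
#' @export
bin_micrograph <- function(micrograph, factor) {
  assert_grid(micrograph, "micrograph")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("binning factor must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) return(micrograph)
  hb <- nrow(micrograph) %/% factor
  wb <- ncol(micrograph) %/% factor
  if (hb < 1L || wb < 1L) stop("binning factor larger than the image", call. = FALSE)
  m <- micrograph[seq_len(hb * factor), seq_len(wb * factor), drop = FALSE]
  # average within rows of each tile, then within columns
  a <- colMeans(array(m, c(factor, hb * factor * wb)))   # rows within tile
  a <- array(a, c(hb, factor, wb))
  a <- colMeans(aperm(a, c(2L, 1L, 3L)))                 # cols within tile
  matrix(a, hb, wb)
}

# stack a list of equally sized square boxes into a (side, side, n) array
as_box_array <- function(boxes) {
  if (is.array(boxes) && length(dim(boxes)) == 3L) return(boxes)
  if (is.matrix(boxes)) return(array(boxes, c(dim(boxes), 1L)))
  stopifnot(is.list(boxes), length(boxes) > 0L)
  side <- nrow(boxes[[1L]])
  arr <- array(0, c(side, side, length(boxes)))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (!is.matrix(b) || nrow(b) != side || ncol(b) != side) {
      stop("all boxes must be square matrices of the same side", call. = FALSE)
    }
    arr[, , i] <- b
  }
  arr
}
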