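# ggplot2 displays for score maps, precision-recall curves and picked
# micrographs.

#' @export
autoplot.score_map <- function(object, ...) {
  df <- tibble(
    x = rep((seq_len(ncol(object$scores)) - 1L) * object$stride,
            each = nrow(object$scores)),
    y = rep((seq_len(nrow(object$scores)) - 1L) * object$stride,
            times = ncol(object$scores)),
    score = as.vector(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "score",
                  title = "Rotation-averaged particle scores")
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  best <- select_threshold(object)
  p <- object$points
  i <- which(p$threshold == best)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$threshold), size = 1.5) +
    ggplot2::geom_point(data = p[i, ], shape = 1, size = 4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision", colour = "threshold",
      title = sprintf("Precision-recall curve (F%g-selected threshold %.2f)",
                      object$beta, best))
}

#' Display a micrograph with picked and true particle boxes
#'
#' Renders the micrograph (downsampled for display if large) in grey scale
#' with picked candidate boxes and, optionally, ground-truth boxes overlaid.
#'
#' @param micrograph Numeric matrix.
#' @param candidates Optional candidate tibble (`x`, `y`).
#' @param truth Optional ground-truth tibble (`x`, `y`).
#' @param box_side Box side in pixels for the overlays; defaults to the
#'   `box_side` attribute of `candidates`.
#' @param max_display Largest displayed side before binning (default 512).
#' @return A ggplot object.
#' @export
plot_micrograph <- function(micrograph, candidates = NULL, truth = NULL,
                            box_side = NULL, max_display = 512L) {
  assert_grid(micrograph, "micrograph")
  if (is.null(box_side) && !is.null(candidates)) {
    box_side <- attr(candidates, "box_side")
  }
  f <- max(1L, ceiling(max(dim(micrograph)) / max_display))
  disp <- bin_micrograph(micrograph, f)
  df <- tibble(
    x = rep((seq_len(ncol(disp)) - 0.5) * f, each = nrow(disp)),
    y = rep((seq_len(nrow(disp)) - 0.5) * f, times = ncol(disp)),
    value = as.vector(disp))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  add_boxes <- function(g, coords, colour) {
    if (is.null(coords) || nrow(coords) == 0L || is.null(box_side)) return(g)
    g + ggplot2::geom_rect(
      data = tibble(xmin = coords$x, xmax = coords$x + box_side,
                    ymin = coords$y, ymax = coords$y + box_side),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
                   ymax = .data$ymax),
      inherit.aes = FALSE, colour = colour, fill = NA, linewidth = 0.4)
  }
  g <- add_boxes(g, truth, "orange")
  add_boxes(g, candidates, "white")
}
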