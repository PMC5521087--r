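# Precision-recall accounting against ground truth and F-beta threshold
# selection.

#' Match picked candidates to ground-truth coordinates
#'
#' Greedy one-to-one matching: candidates are visited in descending score
#' order (ties by raster order) and each claims the nearest still-unclaimed
#' truth coordinate within the tolerance (Euclidean distance between box
#' corners, which equals the centre distance for equal box sizes; exact
#' distance ties go to the lower-index truth). Unmatched candidates count as
#' false positives, unmatched truths as false negatives.
#'
#' @param picked Candidate tibble with `x`, `y` and optionally `score`.
#' @param truth Data frame (or 2-column matrix) of true coordinates `x`, `y`
#'   on the same convention.
#' @param tolerance Maximum match distance in pixels.
#' @return A `match_result` with counts `tp`, `fp`, `fn`, the tolerance, and
#'   a `matches` tibble of claimed (candidate, truth) index pairs.
#' @export
match_candidates <- function(picked, truth, tolerance) {
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }
  if (is.matrix(truth)) truth <- tibble(x = truth[, 1L], y = truth[, 2L])
  n_truth <- if (is.null(truth)) 0L else nrow(truth)
  n_pick <- if (is.null(picked)) 0L else nrow(picked)
  if (n_pick == 0L || n_truth == 0L) {
    return(new_match_result(0L, n_pick, n_truth, tolerance,
                            tibble(candidate = integer(), truth = integer())))
  }
  ord <- if ("score" %in% names(picked)) {
    order(-picked$score, picked$y, picked$x)
  } else {
    seq_len(n_pick)
  }
  claimed <- rep(FALSE, n_truth)
  cand_idx <- integer(0)
  truth_idx <- integer(0)
  for (i in ord) {
    d2 <- (truth$x - picked$x[i])^2 + (truth$y - picked$y[i])^2
    d2[claimed] <- Inf
    j <- which.min(d2)  # lower index wins exact ties
    if (length(j) == 1L && d2[j] <= tolerance^2) {
      claimed[j] <- TRUE
      cand_idx <- c(cand_idx, i)
      truth_idx <- c(truth_idx, j)
    }
  }
  tp <- length(cand_idx)
  new_match_result(tp, n_pick - tp, n_truth - tp, tolerance,
                   tibble(candidate = cand_idx, truth = truth_idx))
}

new_match_result <- function(tp, fp, fn, tolerance, matches,
                             threshold = NA_real_) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 threshold = threshold, tolerance = tolerance,
                 matches = matches),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  pr <- precision_recall(x)
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (tolerance %.1f px): precision %.3f, recall %.3f\n",
              x$tp, x$fp, x$fn, x$tolerance, pr$precision, pr$recall))
  invisible(x)
}

#' Precision and recall of a match result
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. Degenerate
#' denominators are defined as perfect: with no picks there are no false
#' alarms (precision 1), with no truths nothing is missed (recall 1).
#'
#' @param m A `match_result`, or any list with `tp`, `fp`, `fn` counts.
#' @return One-row tibble with `precision` and `recall`.
#' @export
precision_recall <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tibble(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
         recall = if (tp + fn == 0L) 1 else tp / (tp + fn))
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) * precision * recall / (beta^2 * precision +
#' recall)`, the weighted harmonic combination of precision and recall; it
#' reaches its best value at 1 and worst at 0. The default `beta = 2` weights
#' recall higher than precision, the weighting used to select the picking
#' threshold.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @param beta Positive weighting coefficient (default 2).
#' @return The F-beta values; 0 where precision and recall are both 0.
#' @export
f_beta <- function(precision, recall, beta = 2) {
  stopifnot(beta > 0, all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, (1 + beta^2) * precision * recall / den)
}

#' Precision-recall curve over score thresholds
#'
#' Runs the picking pipeline on each micrograph at every threshold, matches
#' the picks against ground truth, aggregates TP/FP/FN across micrographs,
#' and returns precision, recall and F-beta per threshold.
#'
#' Each micrograph is scanned once: the score map and local-maximum mask do
#' not depend on the threshold, so sweeping thresholds over the cached scan
#' is arithmetically identical to re-picking per threshold. The pixel-std
#' band is estimated from the full candidate pool of each micrograph (the
#' lowest threshold) and held fixed across the sweep, so candidate sets are
#' nested and recall is monotone non-increasing in the threshold.
#'
#' @param micrographs A micrograph matrix or list of them.
#' @param truths Ground-truth data frame (columns `x`, `y`) or list of them,
#'   one per micrograph, on the box-corner convention.
#' @param state A `cnn_state` or `cnn_fit`.
#' @param thresholds Ascending thresholds; default 50 evenly spaced values in
#'   (0, 1).
#' @param tolerance Match tolerance in pixels; default a quarter of the box
#'   side.
#' @param beta F-beta weighting (default 2).
#' @param stride,nms_radius,std_k,normalize,rotation_average As in
#'   [pick_particles()].
#' @return A `pr_curve` object; its `points` tibble has one row per
#'   threshold.
#' @export
pr_curve <- function(micrographs, truths, state,
                     thresholds = seq(0.02, 0.98, length.out = 50L),
                     tolerance = NULL, beta = 2, stride = 4L,
                     nms_radius = NULL, std_k = 2, normalize = TRUE,
                     rotation_average = TRUE) {
  state <- as_cnn_state(state)
  if (is.matrix(micrographs)) micrographs <- list(micrographs)
  if (is.data.frame(truths)) truths <- list(truths)
  stopifnot(length(micrographs) == length(truths))
  thresholds <- sort(as.numeric(thresholds))
  if (any(thresholds < 0 | thresholds >= 1)) {
    stop("thresholds must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(tolerance)) tolerance <- state$config$box_side / 4

  # per micrograph: full candidate pool (threshold 0) with stds, band fixed
  pools <- lapply(seq_along(micrographs), function(i) {
    m <- micrographs[[i]]
    if (normalize && state$config$normalize != "box") m <- standardize_grid(m)
    sm <- scan_micrograph(m, state, stride = stride,
                          rotation_average = rotation_average)
    cand <- find_candidates(sm, threshold = 0, nms_radius = nms_radius,
                            micrograph = m)
    if (nrow(cand) >= 2L && !is.null(std_k)) {
      mu <- mean(cand$pixel_std); sig <- stats::sd(cand$pixel_std)
      if (sig > 0) {
        cand <- cand[abs(cand$pixel_std - mu) <= std_k * sig, , drop = FALSE]
      }
    }
    cand
  })

  counts <- lapply(thresholds, function(t) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(pools)) {
      sub <- pools[[i]][pools[[i]]$score >= t, , drop = FALSE]
      m <- match_candidates(sub, truths[[i]], tolerance)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    c(tp = tp, fp = fp, fn = fn)
  })
  counts <- do.call(rbind, counts)
  precision <- ifelse(counts[, "tp"] + counts[, "fp"] == 0, 1,
                      counts[, "tp"] / (counts[, "tp"] + counts[, "fp"]))
  recall <- ifelse(counts[, "tp"] + counts[, "fn"] == 0, 1,
                   counts[, "tp"] / (counts[, "tp"] + counts[, "fn"]))
  points <- tibble(threshold = thresholds,
                   tp = counts[, "tp"], fp = counts[, "fp"], fn = counts[, "fn"],
                   precision = precision, recall = recall,
                   f_beta = f_beta(precision, recall, beta))
  structure(list(points = points, beta = beta, tolerance = tolerance),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, beta = %g, match tolerance %.1f px\n",
              nrow(x$points), x$beta, x$tolerance))
  best <- select_threshold(x)
  i <- which(x$points$threshold == best)
  cat(sprintf("  best F%g = %.3f at threshold %.3f (precision %.3f, recall %.3f)\n",
              x$beta, x$points$f_beta[i], best, x$points$precision[i],
              x$points$recall[i]))
  invisible(x)
}

#' Select the picking threshold by maximal F-beta
#'
#' Returns the threshold at the highest F-beta value on the curve; exact ties
#' are broken toward the higher threshold, favouring precision at equal
#' F-beta.
#'
#' @param curve A [pr_curve()] result.
#' @return The selected threshold.
#' @export
select_threshold <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  p <- curve$points
  if (nrow(p) == 0L) stop("empty precision-recall curve", call. = FALSE)
  best <- which(p$f_beta == max(p$f_beta))
  p$threshold[best[length(best)]]  # points are sorted by threshold
}

#' Area under a precision-recall curve
#'
#' Trapezoidal area over the observed (recall, precision) points, a scalar
#' summary used to compare picking quality across conditions (higher is
#' better).
#'
#' @param curve A [pr_curve()] result.
#' @return The trapezoidal area.
#' @export
pr_auc <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  p <- curve$points[order(curve$points$recall), ]
  r <- c(0, p$recall)
  q <- c(p$precision[1L], p$precision)
  sum(diff(r) * (head(q, -1L) + q[-1L]) / 2)
}

#' @describeIn pr_curve Curve points as a tibble.
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @export
tidy.pr_curve <- function(x, ...) x$points

#' @describeIn pr_curve One-row summary: best threshold, its precision,
#'   recall and F-beta, and the curve area.
#' @export
glance.pr_curve <- function(x, ...) {
  best <- select_threshold(x)
  i <- which(x$points$threshold == best)
  tibble(threshold = best, precision = x$points$precision[i],
         recall = x$points$recall[i], f_beta = x$points$f_beta[i],
         auc = pr_auc(x), beta = x$beta)
}
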