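# Training data assembly, rotation augmentation, and the training loop with
# held-out accuracy feedback.
#
# A training set is an ordinary tibble with one row per sample:
#   box        list-column of square numeric matrices
#   target     1 for particle, 0 for non-particle
#   micrograph identifier of the source micrograph (origin bookkeeping)
#   x, y       0-based corner coordinates of the box in that micrograph
#   rotation   degrees of augmentation rotation applied (0/90/180/270)

#' Assemble labelled training samples
#'
#' @param boxes List of square numeric matrices.
#' @param target 0/1 label per box (recycled if length 1).
#' @param micrograph Source micrograph identifier per box (origin tracking).
#' @param x,y 0-based corner coordinates of each box in its micrograph.
#' @return A training-set tibble (rotation 0, i.e. unaugmented originals).
#' @export
training_samples <- function(boxes, target, micrograph = NA_character_,
                             x = NA_integer_, y = NA_integer_) {
  stopifnot(is.list(boxes), length(boxes) > 0L)
  target <- rep_len(as.integer(target), length(boxes))
  if (!all(target %in% c(0L, 1L))) {
    stop("targets must be 0 (non-particle) or 1 (particle)", call. = FALSE)
  }
  tibble(box = boxes, target = target,
         micrograph = rep_len(as.character(micrograph), length(boxes)),
         x = rep_len(as.integer(x), length(boxes)),
         y = rep_len(as.integer(y), length(boxes)),
         rotation = 0L)
}

#' Augment a training set by quarter-turn rotations
#'
#' Adds exact 90, 180 and 270 degree rotations of every original box,
#' enlarging the set by a factor of four; targets and origins are copied
#' unchanged and the applied rotation is recorded.
#'
#' @param originals Training-set tibble of unaugmented samples (rotation 0).
#' @return The four-fold augmented training-set tibble.
#' @export
augment_rotations <- function(originals) {
  check_training_set(originals)
  if (any(originals$rotation != 0L)) {
    stop("augment_rotations expects unaugmented originals (rotation 0)",
         call. = FALSE)
  }
  sides <- vapply(originals$box, function(b) {
    if (nrow(b) != ncol(b)) stop("boxes must be square to rotate", call. = FALSE)
    nrow(b)
  }, integer(1L))
  stopifnot(length(unique(sides)) == 1L)
  rotated <- lapply(1:3, function(k) {
    out <- originals
    out$box <- lapply(out$box, rotate_grid, k = k)
    out$rotation <- k * 90L
    out
  })
  dplyr::bind_rows(c(list(originals), rotated))
}

check_training_set <- function(samples, what = "training set") {
  if (!is.data.frame(samples) || nrow(samples) == 0L) {
    stop(what, " must be a non-empty training-set tibble", call. = FALSE)
  }
  need <- c("box", "target", "micrograph", "x", "y", "rotation")
  if (!all(need %in% names(samples))) {
    stop(what, " is missing columns: ",
         paste(setdiff(need, names(samples)), collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

origin_keys <- function(samples) {
  paste(samples$micrograph, samples$x, samples$y, sep = "/")
}

#' Enlarge a training set with verified picks
#'
#' The recursive training-set optimization step: manually verified additions
#' from new micrographs (false positives relabelled 0, missed particles
#' labelled 1) are appended, the new originals are rotation-augmented, and the
#' enlarged set is returned. Additions whose origin already occurs in the
#' current set are dropped with a warning.
#'
#' @param current Augmented training-set tibble.
#' @param additions Training-set tibble of unaugmented new originals.
#' @return The enlarged, augmented training-set tibble.
#' @export
refresh_training_set <- function(current, additions) {
  check_training_set(current)
  if (is.null(additions) || nrow(additions) == 0L) return(current)
  check_training_set(additions, "additions")
  dup <- origin_keys(additions) %in% origin_keys(current)
  if (any(dup)) {
    warning(sum(dup), " addition(s) duplicate an existing origin; dropped",
            call. = FALSE)
    additions <- additions[!dup, , drop = FALSE]
  }
  if (nrow(additions) == 0L) return(current)
  dplyr::bind_rows(current, augment_rotations(additions))
}

#' Classification accuracy on a labelled set
#'
#' Scores every sample with the rotation-averaged forward pass ([score_box()])
#' and predicts particle when the score is at or above the threshold (ties
#' count as positive). Returns the fraction of correct predictions.
#'
#' @param state A `cnn_state` or `cnn_fit`.
#' @param samples Training-set tibble.
#' @param threshold Decision threshold in (0, 1).
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(state, samples, threshold = 0.5) {
  state <- as_cnn_state(state)
  check_training_set(samples)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  scores <- score_box_batch(samples$box, state)
  mean((scores >= threshold) == (samples$target == 1L))
}

#' Train the picking network
#'
#' Repeats gradient updates of the half mean squared error over epochs,
#' evaluating accuracy on a disjoint held-out set at threshold 0.5 after each
#' epoch, and stops once the target accuracy (default 0.95) is reached or
#' `max_epochs` expire. Full-batch by default; with a `batch_size` the epoch
#' is split into seeded-shuffle mini-batches. Fully deterministic given the
#' seed.
#'
#' @param train_set,test_set Training-set tibbles; their origins must be
#'   disjoint.
#' @param config A [network_config()].
#' @param eta Learning rate (default 1).
#' @param max_epochs Epoch cap guarding non-convergence.
#' @param target_accuracy Held-out accuracy at which training stops.
#' @param batch_size Mini-batch size, or `NULL` (default) for full batch.
#' @param seed Integer seed covering initialization and shuffling.
#' @return A `cnn_fit` with elements `state` (the trained `cnn_state`) and
#'   `report` (per-epoch losses and accuracies, final accuracy, stop reason).
#' @export
train_picker <- function(train_set, test_set, config, eta = 1,
                         max_epochs = 50L, target_accuracy = 0.95,
                         batch_size = NULL, seed = 1L) {
  check_training_set(train_set)
  check_training_set(test_set, "test set")
  stopifnot(inherits(config, "cnn_config"))
  shared <- intersect(origin_keys(train_set), origin_keys(test_set))
  shared <- shared[!grepl("^NA/", shared)]
  if (length(shared) > 0L) {
    stop("train and test sets share ", length(shared),
         " origin(s); they must be disjoint", call. = FALSE)
  }
  n_pos <- sum(train_set$target == 1L)
  n_neg <- sum(train_set$target == 0L)
  if (abs(n_pos - n_neg) > 0.1 * nrow(train_set)) {
    warning("training set is unbalanced (", n_pos, " positives vs ", n_neg,
            " negatives); the protocol keeps the classes equal", call. = FALSE)
  }

  arr <- maybe_standardize_boxes(as_box_array(train_set$box), config)
  if (dim(arr)[1L] != config$box_side) {
    stop("training boxes must match the configured box side ",
         config$box_side, call. = FALSE)
  }
  targets <- as.numeric(train_set$target)
  n <- length(targets)
  pools <- as.integer(config$pool_sizes)
  acode <- act_code(config)

  epoch_losses <- numeric(0)
  epoch_accuracy <- numeric(0)
  stopped_reason <- "max_epochs"
  state <- NULL

  withr::with_seed(as.integer(seed), {
    state <- init_network(config, seed = sample.int(.Machine$integer.max, 1L))
    for (epoch in seq_len(max_epochs)) {
      if (is.null(batch_size) || batch_size >= n) {
        g <- cpp_backprop_batch(arr, targets, state$params, config$box_side,
                                pools, acode)
        loss <- cnn_loss(g$scores, targets)
        g$scores <- NULL
        if (config$bias == "layer") {
          for (l in 1:3) g$conv[[l]]$b <- rep(sum(g$conv[[l]]$b),
                                              length(g$conv[[l]]$b))
        }
        state <- sgd_update(state, g, eta)
      } else {
        ord <- sample.int(n)
        losses <- numeric(0)
        for (start in seq(1L, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1L, n)]
          g <- cpp_backprop_batch(arr[, , idx, drop = FALSE], targets[idx],
                                  state$params, config$box_side, pools, acode)
          losses <- c(losses, cnn_loss(g$scores, targets[idx]))
          g$scores <- NULL
          if (config$bias == "layer") {
            for (l in 1:3) g$conv[[l]]$b <- rep(sum(g$conv[[l]]$b),
                                                length(g$conv[[l]]$b))
          }
          state <- sgd_update(state, g, eta)
        }
        loss <- mean(losses)
      }
      acc <- evaluate_accuracy(state, test_set, threshold = 0.5)
      epoch_losses <- c(epoch_losses, loss)
      epoch_accuracy <- c(epoch_accuracy, acc)
      if (acc >= target_accuracy) {
        stopped_reason <- "target_accuracy"
        break
      }
    }
  })

  structure(
    list(state = state,
         report = list(epoch_losses = epoch_losses,
                       epoch_accuracy = epoch_accuracy,
                       test_accuracy = epoch_accuracy[length(epoch_accuracy)],
                       stopped_reason = stopped_reason)),
    class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cnn_fit> %d epoch(s), final loss %.5f, held-out accuracy %.3f (%s)\n",
              length(r$epoch_losses), r$epoch_losses[length(r$epoch_losses)],
              r$test_accuracy, r$stopped_reason))
  invisible(x)
}

#' @describeIn train_picker Per-epoch training history as a tibble.
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @export
tidy.cnn_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$report$epoch_losses),
         loss = x$report$epoch_losses,
         test_accuracy = x$report$epoch_accuracy)
}

#' @describeIn train_picker One-row training summary.
#' @export
glance.cnn_fit <- function(x, ...) {
  r <- x$report
  tibble(n_epochs = length(r$epoch_losses),
         final_loss = r$epoch_losses[length(r$epoch_losses)],
         test_accuracy = r$test_accuracy,
         stopped_reason = r$stopped_reason,
         n_parameters = n_parameters(x$state$config))
}
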