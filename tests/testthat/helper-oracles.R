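# Independent brute-force oracles and shared fixtures.  The oracles are
# deliberately naive (double loops, exhaustive enumeration) and never call
# the package's compiled paths.

# valid cross-correlation by explicit double loop
oracle_conv <- function(X, K) {
  k <- nrow(K)
  R <- nrow(X) - k + 1L
  C <- ncol(X) - k + 1L
  out <- matrix(0, R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      acc <- 0
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          acc <- acc + X[i + a - 1L, j + b - 1L] * K[a, b]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# non-overlapping block average by explicit loop
oracle_pool <- function(X, q) {
  R <- nrow(X) %/% q
  C <- ncol(X) %/% q
  out <- matrix(0, R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      blk <- X[(i - 1L) * q + seq_len(q), (j - 1L) * q + seq_len(q)]
      out[i, j] <- mean(blk)
    }
  }
  out
}

# exhaustive best one-to-one assignment restricted to pairs within tolerance;
# used to audit the greedy matcher on tiny configurations
oracle_max_matching <- function(picked, truth, tolerance) {
  np <- nrow(picked)
  nt <- nrow(truth)
  if (np == 0L || nt == 0L) return(0L)
  best <- 0L
  assign_next <- function(i, used, count) {
    if (i > np) {
      best <<- max(best, count)
      return(invisible())
    }
    assign_next(i + 1L, used, count)  # leave candidate i unmatched
    for (j in seq_len(nt)) {
      if (used[j]) next
      d <- sqrt((picked$x[i] - truth$x[j])^2 + (picked$y[i] - truth$y[j])^2)
      if (d <= tolerance) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nt), 0L)
  best
}

# smallest schedule the eight-layer shape grammar admits: 8-pixel box,
# two maps per layer
tiny_config <- function(...) {
  network_config(8L, c(6L, 6L, 4L, 2L, 2L, 1L), rep(2L, 6L), ...)
}

tiny_state <- function(seed = 7L, ...) init_network(tiny_config(...), seed = seed)

# compose the network through the exported per-layer operations (the audited
# slow path, used to cross-check the compiled forward)
compose_forward <- function(box, state) {
  cfg <- state$config
  p <- state$params
  a <- box
  for (l in 1:3) {
    a <- conv_forward(a, p$conv[[l]]$W, p$conv[[l]]$b, cfg$activation)
    a <- pool_forward(a, cfg$pool_sizes[l])
  }
  output_forward(a, p$out$w, p$out$b)
}

random_box <- function(side = 8L) matrix(rnorm(side * side), side, side)

# build a score_map object directly (for candidate-selection unit tests)
manual_score_map <- function(scores, stride = 1L, box_side = 2L) {
  structure(list(scores = scores, stride = as.integer(stride),
                 box_side = as.integer(box_side), origin = c(0L, 0L),
                 micrograph_dim = c(nrow(scores) * stride + box_side,
                                    ncol(scores) * stride + box_side),
                 rotation_average = FALSE),
            class = "score_map")
}

# toy linearly separable box problem: centred blob vs pure noise
toy_problem <- function(seed = 3L) {
  withr::with_seed(seed, {
    pattern <- outer(exp(-((1:8 - 4.5)^2) / 6), exp(-((1:8 - 4.5)^2) / 6))
    mk <- function(n, positive) lapply(seq_len(n), function(i) {
      (if (positive) 3 * pattern else 0) + matrix(rnorm(64, sd = 0.3), 8, 8)
    })
    train <- dplyr::bind_rows(
      training_samples(mk(20, TRUE), 1, micrograph = "a", x = 1:20, y = 1),
      training_samples(mk(20, FALSE), 0, micrograph = "a", x = 1:20, y = 100))
    test <- dplyr::bind_rows(
      training_samples(mk(10, TRUE), 1, micrograph = "b", x = 1:10, y = 1),
      training_samples(mk(10, FALSE), 0, micrograph = "b", x = 1:10, y = 100))
    list(train = augment_rotations(train), test = test)
  })
}
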