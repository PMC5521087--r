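# Synthetic micrographs with exact ground truth.
#
# The simulator emulates the noise-tolerance experiment design: projection-
# like particle signals placed at random positions and continuous rotations
# in a flat field, pixel-wise independent zero-mean Gaussian noise added at a
# controlled signal-to-noise ratio, and (optionally) contaminant patches of
# anomalous variance for the pixel-std filter to remove.
#
# SNR convention (stated prominently because alternatives change the scale):
#   SNR = var(noise-free signal over particle-support pixels) / var(noise),
# the standard variance-ratio definition in single-particle work.

#' Noise-free particle templates
#'
#' Builds smooth projection-like templates on a square box: an annulus (a
#' ring-shaped top view), a soft-edged barrel (a side view), and one or more
#' seeded asymmetric multi-Gaussian blobs. Each template is zero outside its
#' support and is scaled to unit standard deviation over the support, so that
#' placed particles carry comparable signal power. Deterministic given the
#' seed.
#'
#' @param box_side Template side in pixels, at least 16.
#' @param seed Integer seed (the blob shapes are randomized).
#' @param n_templates Number of templates, at least 2 (default 3).
#' @return A `particle_model`: list with `templates` (list of matrices) and
#'   `box_side`.
#' @export
make_templates <- function(box_side = 64L, seed = 1L, n_templates = 3L) {
  box_side <- as.integer(box_side)
  if (box_side < 16L) stop("box_side must be at least 16", call. = FALSE)
  n_templates <- as.integer(n_templates)
  stopifnot(n_templates >= 2L)
  b <- box_side
  ctr <- (b + 1) / 2
  xx <- matrix(rep(seq_len(b) - ctr, each = b), b, b)   # col offsets
  yy <- matrix(rep(seq_len(b) - ctr, times = b), b, b)  # row offsets
  r <- sqrt(xx^2 + yy^2)

  finalize <- function(m) {
    m[m < 1e-3 * max(abs(m))] <- 0  # well-defined support
    s <- m[m != 0]
    if (length(s) > 1L && stats::sd(s) > 0) m <- m / stats::sd(s)
    m
  }

  annulus <- finalize(exp(-((r - 0.28 * b) / (0.07 * b))^2))
  barrel <- finalize(
    (1 / (1 + exp((abs(xx) - 0.30 * b) / (0.03 * b)))) *
    (1 / (1 + exp((abs(yy) - 0.17 * b) / (0.03 * b)))))

  blobs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(max(0L, n_templates - 2L)), function(i) {
      m <- matrix(0, b, b)
      for (g in seq_len(4L)) {
        cx <- runif(1, -0.18, 0.18) * b
        cy <- runif(1, -0.18, 0.18) * b
        w <- runif(1, 0.06, 0.12) * b
        a <- runif(1, 0.5, 1)
        m <- m + a * exp(-(((xx - cx)^2 + (yy - cy)^2) / (2 * w^2)))
      }
      finalize(m)
    })
  })

  structure(list(templates = c(list(annulus, barrel), blobs),
                 box_side = box_side),
            class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  cat(sprintf("<particle_model> %d templates on a %d-pixel box\n",
              length(x$templates), x$box_side))
  invisible(x)
}

#' Specification of a synthetic micrograph
#'
#' @param micrograph_side Side of the square micrograph in pixels.
#' @param n_particles Number of particles to place.
#' @param snr Signal-to-noise ratio: variance of the noise-free signal over
#'   particle-support pixels divided by the noise variance. The
#'   noise-tolerance experiments use 0.01 down to 0.001.
#' @param min_separation Minimum pairwise centre separation in pixels.
#' @param contaminant_rate Expected number of contaminant patches (Poisson);
#'   default 0.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(micrograph_side = 1024L, n_particles = 55L,
                           snr = 0.01, min_separation = 80L,
                           contaminant_rate = 0, seed = 1L) {
  stopifnot(snr > 0, contaminant_rate >= 0, n_particles >= 0)
  structure(list(micrograph_side = as.integer(micrograph_side),
                 n_particles = as.integer(n_particles), snr = snr,
                 min_separation = as.numeric(min_separation),
                 contaminant_rate = contaminant_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Render a synthetic micrograph with known ground truth
#'
#' Places `n_particles` randomly chosen templates at rejection-sampled
#' positions (pairwise centre separation at least `min_separation`, boxes
#' fully inside) and continuous random rotations (bilinear resampling), adds
#' Poisson-many elliptical contaminant patches of anomalous noise variance,
#' and finally adds pixel-wise independent zero-mean Gaussian noise with
#' variance `var(signal over support) / snr`. Bit-identical output for a
#' given model and spec.
#'
#' @param model A [make_templates()] particle model.
#' @param spec A [synthetic_spec()].
#' @return List with `micrograph` (signal + noise), `truth` (tibble of
#'   0-based box-corner `x`, `y` and `template_id`, with contaminant regions
#'   as attribute `contaminants`), and the separate `signal` and `noise`
#'   fields plus `noise_sd`, `signal_var` for calibration audits.
#' @export
render_micrograph <- function(model, spec = synthetic_spec()) {
  stopifnot(inherits(model, "particle_model"), inherits(spec, "synthetic_spec"))
  b <- model$box_side
  side <- spec$micrograph_side
  if (side <= b) stop("micrograph must be larger than the box", call. = FALSE)

  withr::with_seed(spec$seed, {
    # --- placement by rejection sampling
    max_try <- 1000L * max(1L, spec$n_particles)
    xs <- ys <- integer(0)
    tries <- 0L
    while (length(xs) < spec$n_particles) {
      tries <- tries + 1L
      if (tries > max_try) {
        stop("could not place ", spec$n_particles, " particles at separation ",
             spec$min_separation, " after ", max_try, " tries", call. = FALSE)
      }
      x <- sample.int(side - b + 1L, 1L) - 1L
      y <- sample.int(side - b + 1L, 1L) - 1L
      if (length(xs) > 0L &&
          min((xs - x)^2 + (ys - y)^2) < spec$min_separation^2) next
      xs <- c(xs, x); ys <- c(ys, y)
    }
    template_id <- if (spec$n_particles > 0L) {
      sample.int(length(model$templates), spec$n_particles, replace = TRUE)
    } else integer(0)

    # --- noise-free signal field
    signal <- matrix(0, side, side)
    for (i in seq_len(spec$n_particles)) {
      tmpl <- model$templates[[template_id[i]]]
      ang <- runif(1, 0, 360)
      rot <- EBImage::imageData(EBImage::rotate(
        EBImage::Image(tmpl), ang, output.dim = c(b, b), bg.col = 0))
      rows <- ys[i] + seq_len(b)
      cols <- xs[i] + seq_len(b)
      signal[rows, cols] <- signal[rows, cols] + rot
    }
    support <- abs(signal) > 1e-8
    signal_var <- if (any(support)) stats::var(signal[support]) else 0
    noise_sd <- if (signal_var > 0) sqrt(signal_var / spec$snr) else 1

    # --- contaminants: elliptical patches of scaled noise variance
    n_cont <- if (spec$contaminant_rate > 0) rpois(1L, spec$contaminant_rate) else 0L
    cont <- tibble(x = numeric(0), y = numeric(0), a = numeric(0),
                   b = numeric(0), factor = numeric(0))
    scale_field <- NULL
    if (n_cont > 0L) {
      scale_field <- matrix(1, side, side)
      col_i <- matrix(rep(seq_len(side), each = side), side, side)
      row_i <- matrix(rep(seq_len(side), times = side), side, side)
      for (i in seq_len(n_cont)) {
        cx <- runif(1, 1, side); cy <- runif(1, 1, side)
        ax <- runif(1, b / 2, 1.5 * b); ay <- runif(1, b / 2, 1.5 * b)
        fac <- sample(c(3, 0.25), 1L)
        inside <- ((col_i - cx) / ax)^2 + ((row_i - cy) / ay)^2 <= 1
        scale_field[inside] <- fac
        cont <- dplyr::bind_rows(cont, tibble(x = cx - 1, y = cy - 1,
                                              a = ax, b = ay, factor = fac))
      }
    }

    # --- additive noise at the requested variance ratio
    noise <- matrix(rnorm(side * side, 0, noise_sd), side, side)
    if (!is.null(scale_field)) noise <- noise * scale_field

    truth <- tibble(x = xs, y = ys, template_id = template_id)
    attr(truth, "contaminants") <- cont
    list(micrograph = signal + noise, truth = truth, signal = signal,
         noise = noise, noise_sd = noise_sd, signal_var = signal_var)
  })
}

#' Harvest labelled training boxes from a synthetic micrograph
#'
#' Extracts every ground-truth box as a positive sample and `n_negatives`
#' random boxes whose centres lie farther than half a box side from every
#' truth centre as negatives, mirroring the equal-count positive/negative
#' protocol. Seeded and deterministic.
#'
#' @param micrograph The micrograph matrix (extract after any
#'   standardization you intend to train with).
#' @param truth Ground-truth tibble from [render_micrograph()].
#' @param box_side Box side in pixels.
#' @param n_negatives Number of negative boxes (default: as many as there are
#'   truths).
#' @param seed Integer seed.
#' @param micrograph_id Origin identifier recorded with each sample.
#' @return A training-set tibble of unaugmented samples.
#' @export
harvest_training_boxes <- function(micrograph, truth, box_side,
                                   n_negatives = nrow(truth), seed = 1L,
                                   micrograph_id = "synthetic") {
  assert_grid(micrograph, "micrograph")
  b <- as.integer(box_side)
  side_r <- nrow(micrograph); side_c <- ncol(micrograph)
  if (any(truth$x < 0L | truth$y < 0L | truth$x + b > side_c |
          truth$y + b > side_r)) {
    stop("truth boxes do not fit inside the micrograph", call. = FALSE)
  }
  extract <- function(x, y) micrograph[y + seq_len(b), x + seq_len(b)]

  pos <- lapply(seq_len(nrow(truth)),
                function(i) extract(truth$x[i], truth$y[i]))
  neg_xy <- withr::with_seed(as.integer(seed), {
    xs <- ys <- integer(0)
    tries <- 0L
    max_try <- 2000L * max(1L, n_negatives)
    while (length(xs) < n_negatives) {
      tries <- tries + 1L
      if (tries > max_try) {
        stop("could not find ", n_negatives, " negative boxes clear of all ",
             "particles", call. = FALSE)
      }
      x <- sample.int(side_c - b + 1L, 1L) - 1L
      y <- sample.int(side_r - b + 1L, 1L) - 1L
      if (nrow(truth) > 0L &&
          min((truth$x - x)^2 + (truth$y - y)^2) <= (b / 2)^2) next
      xs <- c(xs, x); ys <- c(ys, y)
    }
    list(x = xs, y = ys)
  })
  neg <- lapply(seq_len(n_negatives),
                function(i) extract(neg_xy$x[i], neg_xy$y[i]))

  dplyr::bind_rows(
    training_samples(pos, 1L, micrograph = micrograph_id,
                     x = truth$x, y = truth$y),
    if (n_negatives > 0L) {
      training_samples(neg, 0L, micrograph = micrograph_id,
                       x = neg_xy$x, y = neg_xy$y)
    })
}
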