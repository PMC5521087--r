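# Raster scanning, rotation-averaged scoring and candidate selection.

test_that("score_box is exactly invariant under quarter-turn rotation", {
  st <- tiny_state(seed = 51)
  withr::with_seed(52, box <- random_box())
  s <- score_box(box, st)
  for (k in 1:3) expect_identical(score_box(rotate_grid(box, k), st), s)
  # equals the mean of the four individual forward passes
  manual <- mean(vapply(0:3, function(k) {
    network_forward(rotate_grid(box, k), st)
  }, numeric(1)))
  expect_equal(s, manual, tolerance = 1e-12)
})

test_that("the scan grid has floor((side - box)/stride) + 1 positions per axis", {
  st <- tiny_state(seed = 53)
  withr::with_seed(54, micro <- matrix(rnorm(40 * 50), 40, 50))
  sm <- scan_micrograph(micro, st, stride = 4)
  expect_identical(dim(sm$scores), c((40L - 8L) %/% 4L + 1L,
                                     (50L - 8L) %/% 4L + 1L))
  # the same arithmetic at full benchmark size: 2048-pixel micrograph,
  # 272-pixel box, stride 8 -> 223 positions per axis
  expect_identical((2048L - 272L) %/% 8L + 1L, 223L)
  # stride equal to side - box scans exactly the four corners
  sm2 <- scan_micrograph(micro[, 1:40], st, stride = 32)
  expect_identical(dim(sm2$scores), c(2L, 2L))
  expect_equal(sm2$scores[1, 1], score_box(micro[1:8, 1:8], st))
  expect_equal(sm2$scores[2, 2], score_box(micro[33:40, 33:40], st))
  expect_error(scan_micrograph(micro, st, stride = 0), "positive")
  expect_error(scan_micrograph(micro[1:8, 1:8], st), "larger")
})

test_that("the shared fully-convolutional scan equals the per-box scan", {
  st <- tiny_state(seed = 55)
  cfg <- st$config
  withr::with_seed(56, micro <- matrix(rnorm(40 * 48), 40, 48))
  pools <- as.integer(cfg$pool_sizes)
  for (stride in c(1L, 2L, 4L)) {
    fast <- scan_micrograph(micro, st, stride = stride)$scores
    slow <- cryopick:::cpp_scan_naive(micro, st$params, 8L, pools, 0L,
                                      stride, TRUE)
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
  # without rotation averaging, and on a stride that breaks the rotation grid
  fast1 <- scan_micrograph(micro, st, stride = 3, rotation_average = FALSE)$scores
  slow1 <- cryopick:::cpp_scan_naive(micro, st$params, 8L, pools, 0L, 3L, FALSE)
  expect_lt(max(abs(fast1 - slow1)), 1e-10)
  fast2 <- scan_micrograph(micro, st, stride = 3)$scores
  slow2 <- cryopick:::cpp_scan_naive(micro, st$params, 8L, pools, 0L, 3L, TRUE)
  expect_lt(max(abs(fast2 - slow2)), 1e-10)
})

test_that("a constant-output network yields a constant score map", {
  st <- tiny_state(seed = 57)
  st$params$out$w[] <- 0
  st$params$out$b <- 2
  withr::with_seed(58, micro <- matrix(rnorm(32 * 32), 32, 32))
  sm <- scan_micrograph(micro, st, stride = 4)
  expect_equal(as.vector(sm$scores), rep(sigmoid(2), length(sm$scores)))
})

test_that("candidate selection keeps thresholded strict local maxima", {
  s <- matrix(0.1, 5, 5)
  sm <- manual_score_map(s, stride = 2L, box_side = 4L)
  expect_identical(nrow(find_candidates(sm, 0.5, nms_radius = 2)), 0L)

  s[3, 3] <- 0.9
  sm <- manual_score_map(s, stride = 2L, box_side = 4L)
  got <- find_candidates(sm, 0.5, nms_radius = 2)
  expect_identical(nrow(got), 1L)
  expect_identical(c(got$x, got$y), c(4L, 4L))  # grid index 3 -> pixel 4

  # two peaks: separated by more than the radius both survive, within it only
  # the higher does
  s <- matrix(0.1, 5, 5)
  s[1, 1] <- 0.8; s[5, 5] <- 0.9
  sm <- manual_score_map(s, stride = 2L, box_side = 4L)
  expect_identical(nrow(find_candidates(sm, 0.5, nms_radius = 7)), 2L)
  wide <- find_candidates(sm, 0.5, nms_radius = 8)  # 8 px = 4 grid cells
  expect_identical(nrow(wide), 1L)
  expect_equal(wide$score, 0.9)

  # an exact score tie is broken toward the earlier raster position
  s <- matrix(0.1, 5, 5)
  s[2, 2] <- 0.7; s[2, 4] <- 0.7
  sm <- manual_score_map(s, stride = 2L, box_side = 4L)
  tie <- find_candidates(sm, 0.5, nms_radius = 6)
  expect_identical(nrow(tie), 1L)
  expect_identical(c(tie$x, tie$y), c(2L, 2L))
})

test_that("the pixel-std filter removes outliers but keeps uniform sets", {
  cand <- tibble::tibble(x = 1:11, y = 1:11, score = seq(0.9, 0.5, length.out = 11),
                         pixel_std = c(rep(1, 10), 5))
  kept <- filter_by_std(cand, k = 2)
  # mean 1.364, sd 1.206: the outlier at 5 is 3.01 sd away and is removed
  expect_identical(nrow(kept), 10L)
  expect_true(all(kept$pixel_std == 1))

  same <- cand
  same$pixel_std <- rep(2, 11)
  expect_identical(nrow(filter_by_std(same, k = 2)), 11L)

  expect_identical(filter_by_std(cand, range = c(0, 10)), cand)
  expect_identical(nrow(filter_by_std(cand[1, ], k = 2)), 1L)  # no-op under 2
  expect_error(filter_by_std(cand, k = -1), "positive")
})

test_that("picking is deterministic and a zero threshold with a huge radius keeps one box", {
  st <- tiny_state(seed = 61)
  withr::with_seed(62, micro <- matrix(rnorm(48 * 48), 48, 48))
  one <- pick_particles(micro, st, threshold = 0, stride = 4,
                        nms_radius = 1000, std_k = 1000)
  expect_identical(nrow(one), 1L)
  a <- pick_particles(micro, st, threshold = 0.4, stride = 4)
  b <- pick_particles(micro, st, threshold = 0.4, stride = 4)
  expect_identical(a, b)
  # every candidate's box fits inside the micrograph
  expect_true(all(a$x >= 0 & a$y >= 0 & a$x + 8 <= 48 & a$y + 8 <= 48))
})

test_that("picking commutes with quarter-turn rotation of the micrograph", {
  st <- tiny_state(seed = 63)
  withr::with_seed(64, micro <- matrix(rnorm(48 * 56), 48, 56))
  b <- 8L
  orig <- pick_particles(micro, st, threshold = 0.3, stride = 4, std_k = 1000)
  rot <- pick_particles(rotate_grid(micro, 1L), st, threshold = 0.3,
                        stride = 4, std_k = 1000)
  # clockwise rotation maps internal corner (x, y) to (H - b - y, x)
  mapped <- tibble::tibble(x = nrow(micro) - b - orig$y, y = orig$x,
                           score = orig$score)
  key <- function(d) paste(d$x, d$y, round(d$score, 10))
  expect_setequal(key(mapped), key(rot))
})

test_that("binning block-averages with cropping and preserves the mean", {
  m <- matrix(rnorm(36), 6, 6)
  expect_identical(bin_micrograph(m, 1), m)
  b2 <- bin_micrograph(m, 2)
  expect_identical(dim(b2), c(3L, 3L))
  expect_equal(b2[1, 1], mean(m[1:2, 1:2]))
  expect_equal(mean(b2), mean(m))
  # trailing rows/cols that do not fill a tile are cropped
  m2 <- matrix(rnorm(7 * 9), 7, 9)
  b3 <- bin_micrograph(m2, 3)
  expect_identical(dim(b3), c(2L, 3L))
  expect_equal(b3[2, 3], mean(m2[4:6, 7:9]))
  # benchmark arithmetic: 7420 x 7676 binned 4x gives 1855 x 1919
  expect_identical(dim(bin_micrograph(matrix(0, 7420, 7676), 4)),
                   c(1855L, 1919L))
  expect_error(bin_micrograph(m, 0), "positive")
})
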