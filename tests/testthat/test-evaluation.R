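# Precision-recall accounting, F-beta, and threshold selection.

test_that("matching handles exact hits, misses and empty inputs", {
  truth <- tibble::tibble(x = c(10, 40, 80), y = c(10, 40, 80))
  picked <- tibble::tibble(x = truth$x, y = truth$y, score = c(0.9, 0.8, 0.7))
  m <- match_candidates(picked, truth, tolerance = 5)
  expect_identical(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))

  empty <- picked[0, ]
  m0 <- match_candidates(empty, truth, tolerance = 5)
  expect_identical(c(m0$tp, m0$fp, m0$fn), c(0L, 3L * 0L, 3L))

  m1 <- match_candidates(picked, truth[0, ], tolerance = 5)
  expect_identical(c(m1$tp, m1$fp, m1$fn), c(0L, 3L, 0L))
  expect_error(match_candidates(picked, truth, tolerance = 0), "positive")
})

test_that("a candidate claims the nearer truth; exact ties go to the lower index", {
  # one candidate between two truths, strictly nearer the second
  truth <- tibble::tibble(x = c(0, 10), y = c(0, 0))
  picked <- tibble::tibble(x = 6, y = 0, score = 0.9)
  m <- match_candidates(picked, truth, tolerance = 8)
  expect_identical(m$matches$truth, 2L)
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 1L))
  # exactly equidistant: the lower-index truth is claimed
  picked2 <- tibble::tibble(x = 5, y = 0, score = 0.9)
  m2 <- match_candidates(picked2, truth, tolerance = 8)
  expect_identical(m2$matches$truth, 1L)
})

test_that("greedy matching conserves counts and never double-claims", {
  withr::with_seed(71, {
    for (case in 1:20) {
      nt <- sample(0:6, 1)
      np <- sample(0:6, 1)
      truth <- tibble::tibble(x = runif(nt, 0, 50), y = runif(nt, 0, 50))
      picked <- tibble::tibble(x = runif(np, 0, 50), y = runif(np, 0, 50),
                               score = runif(np))
      m <- match_candidates(picked, truth, tolerance = 15)
      expect_identical(m$tp + m$fn, nt)
      expect_identical(m$tp + m$fp, np)
      expect_identical(anyDuplicated(m$matches$truth), 0L)
      expect_identical(anyDuplicated(m$matches$candidate), 0L)
      # greedy can only be optimal or below the exhaustive best matching
      expect_lte(m$tp, oracle_max_matching(picked, truth, 15))
      # every claimed pair is within tolerance
      if (nrow(m$matches) > 0) {
        d <- sqrt((picked$x[m$matches$candidate] - truth$x[m$matches$truth])^2 +
                  (picked$y[m$matches$candidate] - truth$y[m$matches$truth])^2)
        expect_true(all(d <= 15))
      }
    }
  })
})

test_that("precision and recall follow their definitions with degenerate cases", {
  pr <- precision_recall(list(tp = 8L, fp = 2L, fn = 2L))
  expect_equal(c(pr$precision, pr$recall), c(0.8, 0.8))
  pr1 <- precision_recall(list(tp = 5L, fp = 0L, fn = 0L))
  expect_equal(c(pr1$precision, pr1$recall), c(1, 1))
  pr0 <- precision_recall(list(tp = 0L, fp = 5L, fn = 5L))
  expect_equal(c(pr0$precision, pr0$recall), c(0, 0))
  # degenerate denominators are defined as perfect
  prd <- precision_recall(list(tp = 0L, fp = 0L, fn = 0L))
  expect_equal(c(prd$precision, prd$recall), c(1, 1))
})

test_that("F-beta is the weighted harmonic combination", {
  expect_equal(f_beta(1, 1, 2), 1)
  expect_equal(f_beta(0.5, 1, 2), 5 * 0.5 * 1 / (4 * 0.5 + 1))  # 0.8333...
  for (p in c(0.2, 0.5, 0.9)) {
    for (beta in c(0.5, 1, 2)) expect_equal(f_beta(p, p, beta), p)
  }
  expect_equal(f_beta(0, 0, 2), 0)
  # bounded by min and max of precision and recall when both positive
  withr::with_seed(72, {
    p <- runif(50); r <- runif(50)
    fb <- f_beta(p, r, 2)
    expect_true(all(fb <= pmax(p, r) + 1e-12))
    expect_true(all(fb >= pmin(p, r) - 1e-12))
  })
})

test_that("threshold selection maximizes F-beta with ties to the higher threshold", {
  mk_curve <- function(f) {
    structure(list(points = tibble::tibble(
      threshold = seq(0.1, 0.9, length.out = length(f)),
      tp = 0L, fp = 0L, fn = 0L, precision = 0.5, recall = 0.5, f_beta = f),
      beta = 2, tolerance = 4),
      class = "pr_curve")
  }
  single <- mk_curve(c(0.2, 0.8, 0.5))
  expect_equal(select_threshold(single), 0.5)
  flat <- mk_curve(rep(0.4, 5))
  expect_equal(select_threshold(flat), 0.9)
  tie <- mk_curve(c(0.1, 0.7, 0.3, 0.7, 0.2))
  expect_equal(select_threshold(tie), 0.7)
  expect_equal(select_threshold(tie), max(tie$points$threshold[
    tie$points$f_beta == max(tie$points$f_beta)]))
  expect_error(select_threshold(mk_curve(numeric(0))), "empty")
})

test_that("pr_curve sweeps thresholds with monotone non-increasing recall", {
  st <- tiny_state(seed = 73)
  withr::with_seed(74, {
    micro <- matrix(rnorm(64 * 64), 64, 64)
    truth <- tibble::tibble(x = c(8, 40), y = c(8, 40))
  })
  curve <- pr_curve(micro, truth, st, thresholds = seq(0.05, 0.95, by = 0.05),
                    stride = 4, tolerance = 4)
  p <- curve$points
  expect_identical(nrow(p), 19L)
  expect_true(all(diff(p$recall) <= 1e-12))
  expect_true(all(p$precision >= 0 & p$precision <= 1))
  expect_true(all(p$recall >= 0 & p$recall <= 1))
  # conservation at every threshold
  expect_true(all(p$tp + p$fn == nrow(truth)))
  # a threshold above every score picks nothing: degenerate precision 1
  hi <- p[nrow(p), ]
  if (hi$tp + hi$fp == 0) expect_equal(hi$precision, 1)
  # the selected threshold is the brute-force argmax over the points
  best <- select_threshold(curve)
  expect_equal(max(p$f_beta), p$f_beta[p$threshold == best])
  # broom accessors
  expect_identical(tidy(curve), p)
  expect_identical(glance(curve)$threshold, best)
  expect_gte(pr_auc(curve), 0)
})
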