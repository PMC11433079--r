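make_heatmap <- function(w) {
  structure(list(weights = stats::setNames(w,
                                           as.character(seq_along(w) - 1)),
                 intercept = 0, explained_class = 1L),
            class = "lime_heatmap")
}

test_that("the retention rule is inclusive at the overlap boundary", {
  # 3 bands of 10 px each over a 5x6 frame
  sm <- band_segmap(5, 6, 3)
  h <- make_heatmap(c(0.4, 0.3, 0.2))
  brain <- matrix(0L, 5, 6)
  brain[, 1:2] <- 1L               # segment 0 fully inside
  brain[1:4, 3] <- 1L; brain[1:4, 4] <- 1L  # segment 1: 8/10 inside
  brain[1:3, 5] <- 1L; brain[1:4, 6] <- 1L  # segment 2: 7/10 inside
  ref <- refine(h, sm, binary_mask(brain, "brain"), threshold = 0.8)
  expect_equal(ref$weights[["0"]], 0.4)   # full overlap retained
  expect_equal(ref$weights[["1"]], 0.3)   # exactly 80%: inclusive >=
  expect_equal(ref$weights[["2"]], 0)     # 70%: zeroed
  expect_setequal(ref$retained, c(0L, 1L))
  expect_setequal(ref$dropped, 2L)
})

test_that("threshold 0 is the identity and threshold 1 needs full enclosure", {
  sm <- band_segmap(5, 6, 3)
  h <- make_heatmap(c(0.4, 0.3, 0.2))
  brain <- matrix(0L, 5, 6)
  brain[, 1:2] <- 1L
  brain[1:4, 3:4] <- 1L
  bm <- binary_mask(brain, "brain")
  r0 <- refine(h, sm, bm, threshold = 0)
  expect_equal(r0$weights, h$weights)
  expect_length(r0$dropped, 0)
  r1 <- refine(h, sm, bm, threshold = 1)
  expect_equal(r1$retained, 0L)
  expect_equal(unname(r1$weights[c("1", "2")]), c(0, 0))
})

test_that("retained sets nest monotonically in the threshold", {
  set.seed(13)
  for (case in 1:10) {
    sm <- band_segmap(8, 12, 4)
    h <- make_heatmap(runif(4))
    brain <- binary_mask(matrix(rbinom(96, 1, 0.6), 8, 12), "brain")
    prev <- NULL
    for (t in c(0, 0.25, 0.5, 0.8, 1)) {
      cur <- refine(h, sm, brain, threshold = t)$retained
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("refinement never raises a weight and keeps the support nested", {
  set.seed(23)
  sm <- band_segmap(10, 10, 5)
  h <- make_heatmap(rnorm(5))
  brain <- binary_mask(matrix(rbinom(100, 1, 0.5), 10, 10), "brain")
  ref <- refine(h, sm, brain, 0.8)
  expect_true(all(abs(ref$weights) <= abs(h$weights) + 1e-15))
  expect_true(all(which(ref$weights != 0) %in% which(h$weights != 0)))
  expect_setequal(c(ref$retained, ref$dropped), 0:4)
  expect_length(intersect(ref$retained, ref$dropped), 0)
})

test_that("explanation masks are unions of the selected segments", {
  sm <- band_segmap(6, 9, 3)
  expect_true(all(explanation_mask(sm, 0:2) == 1))
  expect_true(all(explanation_mask(sm, integer(0)) == 0))
  two <- explanation_mask(sm, c(0L, 2L))
  expect_equal(sum(two), sum(segment_sizes(sm)[c(1, 3)]))
  expect_error(explanation_mask(sm, 7L), "unknown")
})

test_that("coverage formulas match brute-force pixel counting", {
  expl_all <- binary_mask(matrix(1L, 8, 8), "explanation")
  tum <- binary_mask(matrix(rbinom(64, 1, 0.3), 8, 8), "tumor")
  expect_equal(tumor_segment_coverage(expl_all, tum), 100)
  none <- binary_mask(matrix(0L, 8, 8), "explanation")
  expect_equal(tumor_segment_coverage(none, tum), 0)
  expect_error(tumor_segment_coverage(expl_all,
                                      binary_mask(matrix(0L, 8, 8),
                                                  "tumor")),
               "empty")

  set.seed(33)
  for (case in 1:40) {
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    expl <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
    ref <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
    if (sum(ref) == 0) ref[1, 1] <- 1L
    expect_equal(
      tumor_segment_coverage(binary_mask(expl, "explanation"),
                             binary_mask(ref, "tumor")),
      oracle_coverage(expl, ref))
  }
})

test_that("worked coverage examples reproduce their printed percentages", {
  # tumor of 200 px with 103 px covered -> 51.5%
  tum <- matrix(0L, 20, 20); tum[1:10, 1:20] <- 1L
  expl <- matrix(0L, 20, 20); expl[1:10, 1:10] <- 1L; expl[1:3, 11] <- 1L
  expect_equal(tumor_segment_coverage(binary_mask(expl, "explanation"),
                                      binary_mask(tum, "tumor")), 51.5)
  # brain of 10000 px with 2192 px covered -> 21.92%
  brain <- matrix(1L, 100, 100)
  expl2 <- matrix(0L, 100, 100); expl2[1:21, 1:100] <- 1L
  expl2[22, 1:92] <- 1L
  expect_equal(brain_segment_coverage(binary_mask(expl2, "explanation"),
                                      binary_mask(brain, "brain")), 21.92)
})

test_that("top-n coverage is monotone in n for a fixed heatmap", {
  set.seed(44)
  sm <- band_segmap(16, 16, 8)
  h <- make_heatmap(runif(8, -0.5, 1))
  tum <- binary_mask(matrix(rbinom(256, 1, 0.3), 16, 16), "tumor")
  if (sum(tum) == 0) tum[1, 1] <- 1L
  prev <- -1
  for (n in 1:8) {
    cov <- coverage_result(h, sm, n, tumor = tum)
    expect_gte(cov$tsc, prev)
    prev <- cov$tsc
  }
})

test_that("refinement lifts the coverage of a distractor-laden heatmap", {
  # segment 2 lies outside the brain but carries the second-largest weight
  sm <- band_segmap(12, 12, 4)
  h <- make_heatmap(c(0.6, 0.2, 0.5, 0.1))
  brain <- matrix(0L, 12, 12); brain[, 1:6] <- 1L
  tum <- matrix(0L, 12, 12); tum[5:8, 2:5] <- 1L
  bm <- binary_mask(brain, "brain")
  tm <- binary_mask(tum, "tumor")
  ref <- refine(h, sm, bm, 0.8)
  before <- coverage_result(h, sm, 2, tumor = tm)$tsc
  after <- coverage_result(ref, sm, 2, tumor = tm)$tsc
  expect_gt(after, before)
})
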