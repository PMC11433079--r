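small_batch <- function(n, seed = 21) {
  generate_batch(n, tiny_phantom_spec(), tumor_fraction = 1, seed = seed)
}

phantom_model <- function(s) bright_region_predictor(s$image)

test_that("the grid yields one record per sample x segmenter x detector x n", {
  samples <- small_batch(2)
  rec <- run_grid(samples, phantom_model, segmenters = "slic",
                  detectors = "otsu", ns = 3L, seed = 1,
                  n_samples = 200, fill = "zero")
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$tsc_before >= 0 & rec$tsc_before <= 100))
  expect_true(all(rec$bsc_after >= 0 & rec$bsc_after <= 100))
  expect_error(run_grid(list(), phantom_model), "empty")
})

test_that("threshold zero refinement leaves coverage untouched", {
  samples <- small_batch(2, seed = 31)
  rec <- run_grid(samples, phantom_model, segmenters = "slic",
                  detectors = "otsu", ns = c(1L, 3L), threshold = 0,
                  seed = 1, n_samples = 200, fill = "zero")
  expect_equal(rec$tsc_after, rec$tsc_before)
  expect_equal(rec$bsc_after, rec$bsc_before)
})

test_that("tumor-negative samples are skipped and reported", {
  samples <- generate_batch(4, tiny_phantom_spec(), tumor_fraction = 0.5,
                            seed = 7)
  # the brightness model sees no tumor mass on negatives once thresholded
  model <- function(s) {
    region <- binary_mask(unclass(s$tumor_truth) * 0L + 1L, "explanation")
    p <- if (s$label == 1) 0.9 else 0.2
    brainlime:::new_predictor(function(images) {
      cbind(rep(1 - p, length(images)), rep(p, length(images)))
    })
  }
  rec <- run_grid(samples, model, segmenters = "slic", detectors = "otsu",
                  ns = 3L, seed = 2, n_samples = 100, fill = "zero")
  expect_length(attr(rec, "skipped"), 2)
  expect_equal(length(unique(rec$image_id)), 2)
})

test_that("grid records are invariant to sample order", {
  samples <- small_batch(2, seed = 13)
  rec_ab <- run_grid(samples, phantom_model, segmenters = "slic",
                     detectors = c("otsu", "li"), ns = 3L, seed = 5,
                     n_samples = 150, fill = "zero")
  rec_ba <- run_grid(rev(samples), phantom_model, segmenters = "slic",
                     detectors = c("otsu", "li"), ns = 3L, seed = 5,
                     n_samples = 150, fill = "zero")
  attr(rec_ab, "skipped") <- NULL
  attr(rec_ba, "skipped") <- NULL
  expect_equal(rec_ab, rec_ba)
})

test_that("summaries average records and filter small deltas", {
  rec <- data.frame(
    image_id = c("a", "b", "a", "b", "c"),
    segmenter = "slic", detector = "otsu",
    n = c(3L, 3L, 5L, 5L, 3L),
    tsc_before = c(40, 60, 10, 20, 50),
    tsc_after = c(40.5, 62, 7, 20.1, 50),
    bsc_before = c(10, 20, 30, 40, 15),
    bsc_after = c(10, 18, 28, 39, 15),
    fallback_used = FALSE, seed = 1L, stringsAsFactors = FALSE
  )
  rep_ <- summarize_records(rec)
  gm3 <- rep_$group_means[rep_$group_means$n == 3, ]
  expect_equal(gm3$tsc_before, 50)
  expect_equal(gm3$tsc_after, mean(c(40.5, 62, 50)))
  # recomputing the mean from raw records matches to near machine precision
  expect_equal(gm3$tsc_after,
               mean(rec$tsc_after[rec$n == 3]), tolerance = 1e-9)
  deltas <- rep_$deltas$delta[rep_$deltas$n == 3]
  expect_equal(sort(deltas), sort(c(0.5, 2, 0)))
  expect_equal(rep_$deltas_filtered$delta[rep_$deltas_filtered$n == 3], 2)
  expect_equal(sort(rep_$deltas_filtered$delta), sort(c(2, -3)))

  one <- summarize_records(rec[1, ])
  expect_equal(one$group_means$tsc_before, 40)
})

test_that("rank-sum comparison behaves on identical and separated samples", {
  x <- c(1, 2, 3, 4, 5)
  res_same <- compare_paired(x, x)
  expect_gt(res_same$p_value, 0.9)
  a <- 1:10; b <- 101:110
  res_sep <- compare_paired(a, b)
  expect_lt(res_sep$p_value, 0.01)
  # rank-based: invariant to a common monotone transform
  res_log <- compare_paired(log(a), log(b))
  expect_equal(res_sep$p_value, res_log$p_value)
  expect_equal(res_sep$statistic, res_log$statistic)
  expect_error(compare_paired(1:2, 1:5), "at least 3")
})

test_that("the omnibus test matches the rank-sum test with two groups", {
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12) + 0.5
  res <- compare_combinations(list(A = a, B = b))
  # with two groups and no ties, H equals the squared normal rank-sum score
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  z <- (wt$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(unname(res$kruskal$statistic), unname(z^2),
               tolerance = 1e-10)
  expect_equal(res$kruskal$p_value,
               stats::pchisq(unname(z^2), 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 1)
  expect_equal(res$pairwise$mean_diff, mean(a) - mean(b))
  expect_error(compare_combinations(list(A = a)), "at least 2")
})

test_that("a strongly shifted group is detected by the omnibus test", {
  set.seed(41)
  hits <- 0
  for (i in 1:50) {
    groups <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, mean = 1))
    if (compare_combinations(groups)$kruskal$p_value < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 45)
})

test_that("reports land on disk with tables, deltas and stats", {
  d <- withr::local_tempdir()
  samples <- small_batch(3, seed = 17)
  rec <- run_grid(samples, phantom_model,
                  segmenters = c("slic", "quickshift"),
                  detectors = c("otsu", "li"), ns = c(1L, 3L), seed = 4,
                  n_samples = 150, fill = "zero")
  write_report(rec, d)
  expect_true(file.exists(file.path(d, "records.csv")))
  expect_true(file.exists(file.path(d, "tables", "tsc_slic.csv")))
  expect_true(file.exists(file.path(d, "tables", "bsc_quickshift.csv")))
  expect_true(file.exists(file.path(d, "deltas.csv")))
  expect_true(file.exists(file.path(d, "stats.json")))
  tab <- utils::read.csv(file.path(d, "tables", "tsc_slic.csv"))
  expect_true(all(c("edge_detector", "n", "no_refinement", "refined") %in%
                    names(tab)))
})

test_that("combo codes follow the detector_segmenter scheme", {
  expect_equal(brainlime:::combo_code("otsu", "slic"), "OTS_SL")
  expect_equal(brainlime:::combo_code("canny", "quickshift"), "CE_QUI")
  expect_equal(brainlime:::combo_code("laplace", "felzenszwalb"),
               "LA_FEL")
})
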