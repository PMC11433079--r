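test_that("perturbation sets start from the original and are seeded", {
  p1 <- sample_perturbations(1, 10, seed = 3)
  expect_equal(p1$presence[1, ], 1L)
  expect_true(all(p1$presence %in% c(0L, 1L)))

  p <- sample_perturbations(8, 1000, seed = 3)
  expect_equal(p$presence[1, ], rep(1L, 8))
  freqs <- colMeans(p$presence[-1, ])
  expect_true(all(abs(freqs - 0.5) < 0.05))

  expect_identical(sample_perturbations(8, 1000, seed = 3)$presence,
                   p$presence)
  expect_false(identical(sample_perturbations(8, 1000, seed = 4)$presence,
                         p$presence))
  expect_error(sample_perturbations(5, 1), "at least 2")
})

test_that("applying a perturbation occludes exactly the dropped segments", {
  set.seed(2)
  img <- matrix(runif(12 * 12), 12, 12)
  sm <- band_segmap(12, 12, 3)
  expect_identical(apply_perturbation(img, sm, c(1, 1, 1)), img)
  expect_true(all(apply_perturbation(img, sm, c(0, 0, 0),
                                     fill = "zero") == 0))

  out <- apply_perturbation(img, sm, c(1, 0, 1), fill = "segment_mean")
  seg1 <- sm$labels == 1L
  expect_equal(unique(out[seg1]), mean(img[seg1]))
  expect_identical(out[!seg1], img[!seg1])
  expect_error(apply_perturbation(img, sm, c(1, 0)), "length")
})

test_that("the surrogate equals the independent weighted-ridge oracle", {
  set.seed(6)
  for (d in 2:4) {
    # full enumeration of presence patterns
    grid <- as.matrix(expand.grid(rep(list(0:1), d)))
    dimnames(grid) <- NULL
    grid <- rbind(rep(1L, d), grid)
    pset <- structure(list(presence = grid, n_samples = nrow(grid),
                           seed = 0L), class = "perturbation_set")
    y <- runif(nrow(grid))
    for (lambda in c(1e-8, 1)) {
      hm <- fit_surrogate(pset, y, kernel_width = 0.25, ridge = lambda)
      wts <- exp(-brainlime:::cosine_dist_to_ones(grid)^2 / 0.25^2)
      orc <- oracle_ridge(grid, y, wts, lambda)
      expect_equal(unname(hm$weights), unname(orc$weights),
                   tolerance = 1e-8)
      expect_equal(hm$intercept, unname(orc$intercept), tolerance = 1e-8)
    }
  }
})

test_that("exactly linear responses are recovered and flat ones vanish", {
  pset <- sample_perturbations(3, 400, seed = 5)
  truth <- c(0.5, -0.2, 0.3)
  y <- 0.2 + pset$presence %*% truth
  hm <- fit_surrogate(pset, as.numeric(y), ridge = 1e-10)
  expect_equal(unname(hm$weights), truth, tolerance = 1e-6)

  flat <- fit_surrogate(pset, rep(0.9, 400))
  expect_lt(max(abs(flat$weights)), 1e-6)

  # d = 2, response = presence of segment 0
  p2 <- sample_perturbations(2, 200, seed = 9)
  h2 <- fit_surrogate(p2, p2$presence[, 1] * 1.0, ridge = 1e-10)
  expect_equal(unname(h2$weights), c(1, 0), tolerance = 1e-6)
})

test_that("top-n selection keeps positives, orders by weight, breaks ties by id", {
  h <- structure(list(weights = c("0" = 0.5, "1" = 0.3, "2" = -0.2,
                                  "3" = 0.1)),
                 class = "lime_heatmap")
  expect_equal(top_n_segments(h, 3), c(0L, 1L, 3L))
  expect_equal(top_n_segments(h, 10), c(0L, 1L, 3L))
  neg <- structure(list(weights = c("0" = -1, "1" = -0.5, "2" = -2)),
                   class = "lime_heatmap")
  expect_length(top_n_segments(neg, 3), 0)
  tie <- structure(list(weights = c("7" = 0.4, "2" = 0.4)),
                   class = "lime_heatmap")
  expect_equal(top_n_segments(tie, 1), 2L)
})

test_that("explanations recover a planted signal and are deterministic", {
  img <- brainlime:::with_seed(10, matrix(runif(48 * 48), 48, 48))
  sm <- segment_image(img, "slic", params = list(n_segments = 9))
  target <- 4L
  pred <- oracle_linear_predictor(sm, stats::setNames(0.7, target),
                                  intercept = 0.2, reference = img)
  hm <- explain_image(img, pred, segmap = sm, n_samples = 600, seed = 2)
  expect_equal(top_n_segments(hm, 1), target)

  hm2 <- explain_image(img, pred, segmap = sm, n_samples = 600, seed = 2)
  expect_identical(hm$weights, hm2$weights)

  # flat model: no segment stands out
  region <- binary_mask(matrix(1L, 48, 48), "explanation")
  flat <- intensity_predictor(region, threshold = -10, sharpness = 0)
  hm3 <- explain_image(img, flat, segmap = sm, n_samples = 200, seed = 3,
                       require_positive = FALSE)
  expect_lt(max(abs(hm3$weights)), 1e-8)
})

test_that("weight ranking is invariant to segment relabeling", {
  img <- brainlime:::with_seed(20, matrix(runif(30 * 30), 30, 30))
  sm <- band_segmap(30, 30, 5)
  perm <- c(3L, 0L, 4L, 1L, 2L)  # old id -> new id
  sm_perm <- structure(list(labels = matrix(perm[sm$labels + 1L], 30, 30),
                            d = 5L, algorithm = "slic", params = list()),
                       class = "segment_map")
  pred <- oracle_linear_predictor(sm, c("1" = 0.4, "3" = 0.2), 0.1, img)
  pred_p <- oracle_linear_predictor(sm_perm,
                                    stats::setNames(c(0.4, 0.2),
                                                    perm[c(2, 4)]),
                                    0.1, img)
  hm <- explain_image(img, pred, segmap = sm, n_samples = 500, seed = 6)
  hm_p <- explain_image(img, pred_p, segmap = sm_perm, n_samples = 500,
                        seed = 6)
  expect_equal(perm[top_n_segments(hm, 2) + 1L], top_n_segments(hm_p, 2))
})

test_that("tumor-negative images are refused unless explicitly allowed", {
  img <- matrix(0.1, 20, 20)
  region <- binary_mask(matrix(1L, 20, 20), "explanation")
  pred <- intensity_predictor(region, threshold = 0.9, sharpness = 20)
  expect_error(explain_image(img, pred, segmap = band_segmap(20, 20, 2),
                             n_samples = 50, seed = 1),
               "tumor-negative")
  hm <- explain_image(img, pred, segmap = band_segmap(20, 20, 2),
                      n_samples = 50, seed = 1, require_positive = FALSE)
  expect_s3_class(hm, "lime_heatmap")
})

test_that("heatmaps and segment maps round-trip through their files", {
  d <- withr::local_tempdir()
  h <- structure(list(weights = c("0" = 0.25, "1" = -0.5, "2" = 0),
                      intercept = 0.4, explained_class = 1L),
                 class = "lime_heatmap")
  write_heatmap_json(h, file.path(d, "h.json"))
  back <- read_heatmap_json(file.path(d, "h.json"))
  expect_equal(back$weights, h$weights)
  expect_equal(back$intercept, h$intercept)

  sm <- band_segmap(9, 12, 4)
  write_segments_tsv(sm, file.path(d, "s.tsv"))
  sm2 <- read_segments_tsv(file.path(d, "s.tsv"))
  expect_identical(sm2$labels, sm$labels)
  expect_equal(sm2$d, sm$d)
})
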