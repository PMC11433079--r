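# Batch experiment harness: segmenter x detector x top-n grid with
# before/after coverage, summary tables, and rank-based statistics.

detector_codes <- c(canny = "CE", laplace = "LA", li = "LI", otsu = "OTS",
                    sobel = "SO")
segmenter_codes <- c(slic = "SL", quickshift = "QUI", felzenszwalb = "FEL")

combo_code <- function(detector, segmenter) {
  paste0(detector_codes[[detector]], "_", segmenter_codes[[segmenter]])
}

#' Run the full evaluation grid
#'
#' For every tumor-positive sample, computes one explanation per
#' segmenter (shared across detectors and `n`, so the before/after arms
#' compare the same heatmap), one brain mask per detector, and records
#' Tumor/Brain Segment Coverage of the top-`n` segments before and after
#' refinement for every combination.
#'
#' Samples the model scores tumor-negative are skipped and reported in the
#' `"skipped"` attribute, keeping denominators transparent.
#'
#' @param samples List of `phantom_sample`s, or of lists with elements
#'   `image` (unit-range image), `tumor` ([binary_mask()]), optional
#'   `id`.
#' @param model A predictor, or a factory `function(sample)` returning a
#'   per-sample predictor.
#' @param segmenters Character vector of segmentation algorithms.
#' @param detectors Character vector of brain-mask detectors.
#' @param ns Integer vector of top-n values (default `c(1, 3, 5)`).
#' @param threshold Refinement overlap threshold (default 0.8).
#' @param seed Top-level seed; per-image substreams are derived by a
#'   stable hash of the image id, so results are invariant to sample
#'   order.
#' @param n_samples Perturbations per explanation (default 1000).
#' @param fill Occlusion fill policy passed to [explain_image()].
#' @param segmenter_params,detector_params Optional named lists (by
#'   algorithm) of parameter overrides.
#' @return A data.frame of evaluation records (one row per sample x
#'   segmenter x detector x n) with attribute `"skipped"`.
#' @export
run_grid <- function(samples, model,
                     segmenters = c("quickshift", "slic"),
                     detectors = c("canny", "laplace", "li", "otsu",
                                   "sobel"),
                     ns = c(1L, 3L, 5L), threshold = 0.8, seed = 1L,
                     n_samples = 1000L, fill = c("segment_mean", "zero"),
                     segmenter_params = list(), detector_params = list()) {
  fill <- match.arg(fill)
  if (length(samples) == 0 || length(segmenters) == 0 ||
      length(detectors) == 0 || length(ns) == 0) {
    stop("empty evaluation grid", call. = FALSE)
  }
  if (is.null(names(samples))) {
    names(samples) <- sprintf("sample_%03d", seq_along(samples))
  }
  rows <- list()
  skipped <- character(0)
  for (id in names(samples)) {
    s <- samples[[id]]
    img <- as_unit_image(s$image)
    tumor <- s[["tumor_truth"]]
    if (is.null(tumor)) tumor <- s[["tumor"]]
    pred <- if (inherits(model, "predictor")) model else model(s)
    if (predict_proba(pred, list(img))[1, 2] < 0.5) {
      skipped <- c(skipped, id)
      next
    }
    sub_seed <- (seed + stable_hash(id)) %% 2147483647
    for (sg in segmenters) {
      hm <- explain_image(img, pred, algorithm = sg,
                          params = segmenter_params[[sg]] %||% list(),
                          n_samples = n_samples, seed = sub_seed,
                          fill = fill)
      segmap <- attr(hm, "segmap")
      for (det in detectors) {
        rep_ <- build_brain_mask(img, detector = det,
                                 params = detector_params[[det]] %||%
                                   list())
        ref <- refine(hm, segmap, rep_$mask, threshold = threshold)
        for (n in ns) {
          before <- coverage_result(hm, segmap, n, tumor = tumor,
                                    brain = rep_$mask)
          after <- coverage_result(ref, segmap, n, tumor = tumor,
                                   brain = rep_$mask)
          rows[[length(rows) + 1L]] <- data.frame(
            image_id = id, segmenter = sg, detector = det, n = n,
            tsc_before = before$tsc, tsc_after = after$tsc,
            bsc_before = before$bsc, bsc_after = after$bsc,
            fallback_used = rep_$fallback_used, seed = sub_seed,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    stop("no tumor-positive samples to evaluate", call. = FALSE)
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$image_id, records$segmenter,
                           records$detector, records$n), ]
  rownames(records) <- NULL
  attr(records, "skipped") <- skipped
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize evaluation records
#'
#' Group means per (segmenter, detector, n), the per-combination delta
#' distributions `tsc_after - tsc_before`, and the subset of deltas whose
#' magnitude exceeds 1 percentage point (minimal-variation images
#' removed).
#'
#' @param records Output of [run_grid()].
#' @return A `comparison_report`: list with `group_means` (data.frame),
#'   `deltas` (data.frame with `combo`, `n`, `image_id`, `delta`),
#'   `deltas_filtered` (same, `|delta| > 1`).
#' @export
summarize_records <- function(records) {
  stopifnot(nrow(records) > 0)
  key <- interaction(records$segmenter, records$detector, records$n,
                     drop = TRUE)
  agg <- function(col) tapply(records[[col]], key, mean)
  first <- function(col) tapply(records[[col]], key,
                                function(v) v[1])
  group_means <- data.frame(
    segmenter = as.character(first("segmenter")),
    detector = as.character(first("detector")),
    n = as.integer(first("n")),
    tsc_before = as.numeric(agg("tsc_before")),
    tsc_after = as.numeric(agg("tsc_after")),
    bsc_before = as.numeric(agg("bsc_before")),
    bsc_after = as.numeric(agg("bsc_after")),
    n_images = as.integer(tapply(records$image_id, key,
                                 function(v) length(unique(v)))),
    stringsAsFactors = FALSE
  )
  group_means <- group_means[order(group_means$segmenter,
                                   group_means$detector, group_means$n), ]
  rownames(group_means) <- NULL
  deltas <- data.frame(
    combo = mapply(combo_code, records$detector, records$segmenter),
    segmenter = records$segmenter, detector = records$detector,
    n = records$n, image_id = records$image_id,
    delta = records$tsc_after - records$tsc_before,
    stringsAsFactors = FALSE
  )
  rownames(deltas) <- NULL
  structure(list(group_means = group_means, deltas = deltas,
                 deltas_filtered = deltas[abs(deltas$delta) > 1, ]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  gm <- x$group_means
  gm[, 4:7] <- round(gm[, 4:7], 2)
  print(gm)
  invisible(x)
}

#' Two-sample rank-sum comparison
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test between two metric
#' vectors (e.g. F1 scores of two classifiers across folds).
#'
#' @param metric_a,metric_b Numeric vectors, each of length >= 3.
#' @return List with `statistic` (U) and `p_value`.
#' @export
compare_paired <- function(metric_a, metric_b) {
  if (length(metric_a) < 3 || length(metric_b) < 3) {
    stop("each metric vector needs at least 3 values", call. = FALSE)
  }
  ht <- suppressWarnings(stats::wilcox.test(metric_a, metric_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare refinement deltas across combinations
#'
#' Omnibus Kruskal-Wallis test over the per-combination delta
#' distributions, plus all pairwise rank-sum comparisons with mean
#' differences; raw p-values are reported alongside Holm-adjusted ones.
#'
#' @param deltas_by_combo Named list (combo code -> numeric vector of
#'   deltas); at least 2 combos with >= 3 values each.
#' @return List with `kruskal` (statistic, df, p_value) and `pairwise`
#'   (data.frame: combo_a, combo_b, mean_diff, p_value, p_holm).
#' @export
compare_combinations <- function(deltas_by_combo) {
  if (length(deltas_by_combo) < 2) {
    stop("need at least 2 combinations to compare", call. = FALSE)
  }
  if (any(vapply(deltas_by_combo, length, 1L) < 3)) {
    stop("each combination needs at least 3 delta values", call. = FALSE)
  }
  values <- unlist(deltas_by_combo, use.names = FALSE)
  groups <- factor(rep(names(deltas_by_combo),
                       vapply(deltas_by_combo, length, 1L)))
  kw <- stats::kruskal.test(values, groups)
  combos <- names(deltas_by_combo)
  pairs <- utils::combn(combos, 2)
  pw <- data.frame(
    combo_a = pairs[1, ], combo_b = pairs[2, ],
    mean_diff = apply(pairs, 2, function(p) {
      mean(deltas_by_combo[[p[1]]]) - mean(deltas_by_combo[[p[2]]])
    }),
    p_value = apply(pairs, 2, function(p) {
      suppressWarnings(stats::wilcox.test(deltas_by_combo[[p[1]]],
                                          deltas_by_combo[[p[2]]]))$p.value
    }),
    stringsAsFactors = FALSE
  )
  pw$p_holm <- stats::p.adjust(pw$p_value, method = "holm")
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pw)
}

#' Write a full evaluation report to disk
#'
#' Emits `records.csv` (raw records), per-segmenter TSC/BSC mean tables
#' (`tables/tsc_<segmenter>.csv`, `tables/bsc_<segmenter>.csv`),
#' `deltas.csv`, and `stats.json` (Kruskal-Wallis + pairwise rank tests on
#' the filtered deltas, per top-n).
#'
#' @param records Output of [run_grid()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(records, dir) {
  dir.create(file.path(dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  rep_ <- summarize_records(records)
  for (sg in unique(rep_$group_means$segmenter)) {
    gm <- rep_$group_means[rep_$group_means$segmenter == sg, ]
    tsc <- data.frame(edge_detector = gm$detector, n = gm$n,
                      no_refinement = round(gm$tsc_before, 2),
                      refined = round(gm$tsc_after, 2))
    bsc <- data.frame(edge_detector = gm$detector, n = gm$n,
                      refined = round(gm$bsc_after, 2))
    write.csv(tsc, file.path(dir, "tables",
                             sprintf("tsc_%s.csv", sg)), row.names = FALSE)
    write.csv(bsc, file.path(dir, "tables",
                             sprintf("bsc_%s.csv", sg)), row.names = FALSE)
  }
  write.csv(rep_$deltas, file.path(dir, "deltas.csv"), row.names = FALSE)
  stats_out <- list()
  for (n in unique(rep_$deltas$n)) {
    dn <- rep_$deltas_filtered[rep_$deltas_filtered$n == n, ]
    by_combo <- split(dn$delta, dn$combo)
    by_combo <- by_combo[vapply(by_combo, length, 1L) >= 3]
    if (length(by_combo) >= 2) {
      stats_out[[paste0("top_", n)]] <- compare_combinations(by_combo)
    }
  }
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
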