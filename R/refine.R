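# The refinement rule and the coverage metrics: the package's core.

#' Refine a heatmap against the brain mask
#'
#' For every segment `Si`, counts the pixels of `Si` lying inside the
#' brain mask; the segment keeps its importance iff
#' `|Si n BrM| >= threshold * |Si|` (inclusive: a segment with exactly the
#' threshold fraction inside is retained), and its importance is set to 0
#' otherwise. The default threshold of 0.8 sits at the sweet spot between
#' keeping out-of-brain clutter (low thresholds) and discarding boundary
#' segments that only marginally leave the brain (high thresholds).
#'
#' @param h A `lime_heatmap` (see [explain_image()]).
#' @param segmap The [segment_image()] label map the heatmap refers to.
#' @param brain A [binary_mask()] brain mask of the same shape.
#' @param threshold Required overlap fraction in \[0, 1\] (default 0.8).
#' @return A `refined_heatmap`: list with `weights` (dropped segments at
#'   0), `retained` and `dropped` (integer id vectors), `threshold`.
#' @export
refine <- function(h, segmap, brain, threshold = 0.8) {
  stopifnot(inherits(segmap, "segment_map"))
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  bpx <- if (inherits(brain, "binary_mask")) mask_pixels(brain) else brain
  if (!all(dim(bpx) == dim(segmap$labels))) {
    stop("brain mask and segment map shapes differ", call. = FALSE)
  }
  lab1 <- as.integer(segmap$labels) + 1L
  sizes <- tabulate(lab1, segmap$d)
  overlap <- tabulate(lab1[bpx == 1L], segmap$d)
  # inclusive >= with a small slack so e.g. 8 >= 0.8 * 10 holds in doubles
  keep <- overlap >= threshold * sizes - 1e-9
  ids <- seq_len(segmap$d) - 1L
  w <- h$weights[as.character(ids)]
  w[is.na(w)] <- 0  # segments absent from the heatmap carry no importance
  w[!keep] <- 0
  names(w) <- as.character(ids)
  structure(list(weights = w, retained = ids[keep], dropped = ids[!keep],
                 threshold = threshold),
            class = c("refined_heatmap", "lime_heatmap"))
}

#' @export
print.refined_heatmap <- function(x, ...) {
  cat(sprintf("<refined_heatmap: %d retained / %d dropped at threshold %.2f>\n",
              length(x$retained), length(x$dropped), x$threshold))
  invisible(x)
}

#' Union mask of selected segments
#'
#' @param segmap A [segment_image()] label map.
#' @param selected Integer vector of segment ids (0-based); may be empty.
#' @return A [binary_mask()] with role `"explanation"`.
#' @export
explanation_mask <- function(segmap, selected) {
  stopifnot(inherits(segmap, "segment_map"))
  selected <- as.integer(selected)
  if (length(selected) > 0 &&
      !all(selected %in% (seq_len(segmap$d) - 1L))) {
    stop("`selected` contains unknown segment ids", call. = FALSE)
  }
  px <- matrix(as.integer(segmap$labels %in% selected),
               nrow(segmap$labels), ncol(segmap$labels))
  binary_mask(px, "explanation")
}

coverage_pct <- function(expl, ref, ref_name) {
  pe <- if (inherits(expl, "binary_mask")) mask_pixels(expl) else expl
  pr <- if (inherits(ref, "binary_mask")) mask_pixels(ref) else ref
  if (!all(dim(pe) == dim(pr))) {
    stop("mask shapes differ", call. = FALSE)
  }
  denom <- sum(pr)
  if (denom == 0) {
    stop(sprintf("%s mask is empty; coverage undefined", ref_name),
         call. = FALSE)
  }
  100 * sum(pe * pr) / denom
}

#' Tumor Segment Coverage (TSC)
#'
#' Percentage of tumor-mask pixels contained in the explanation mask:
#' `100 * |expl n tumor| / |tumor|`. Higher is better — more of the tumor
#' is shown to the user.
#'
#' @param expl Explanation mask (union of selected segments).
#' @param tumor Non-empty tumor mask of the same shape.
#' @return Percentage in \[0, 100\].
#' @export
tumor_segment_coverage <- function(expl, tumor) {
  coverage_pct(expl, tumor, "tumor")
}

#' Brain Segment Coverage (BSC)
#'
#' Percentage of brain-mask pixels contained in the explanation mask:
#' `100 * |expl n brain| / |brain|`. At a fixed TSC, lower is better — the
#' explanation is more specific, flagging less healthy tissue.
#'
#' @param expl Explanation mask.
#' @param brain Non-empty brain mask of the same shape.
#' @return Percentage in \[0, 100\].
#' @export
brain_segment_coverage <- function(expl, brain) {
  coverage_pct(expl, brain, "brain")
}

#' Coverage of a top-n selection
#'
#' Convenience wrapper: selects the top `n` segments of a (possibly
#' refined) heatmap, forms the explanation mask, and scores TSC/BSC.
#'
#' @param h A `lime_heatmap` or `refined_heatmap`.
#' @param segmap The segment label map.
#' @param n Number of segments to select.
#' @param tumor Optional tumor mask (TSC reported when given).
#' @param brain Optional brain mask (BSC reported when given).
#' @return A `coverage_result`: list with `tsc`, `bsc` (NA when the
#'   corresponding mask is absent), `n_selected`, `explanation_pixels`.
#' @export
coverage_result <- function(h, segmap, n, tumor = NULL, brain = NULL) {
  sel <- top_n_segments(h, n)
  expl <- explanation_mask(segmap, sel)
  structure(list(
    tsc = if (is.null(tumor)) NA_real_ else
      tumor_segment_coverage(expl, tumor),
    bsc = if (is.null(brain)) NA_real_ else
      brain_segment_coverage(expl, brain),
    n_selected = length(sel),
    explanation_pixels = sum(mask_pixels(expl))
  ), class = "coverage_result")
}
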