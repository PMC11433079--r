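# Mock predictors satisfying the binary-classifier contract: a predictor
# is a function taking a list of unit-range image matrices and returning an
# n x 2 matrix of class probabilities (p_no_tumor, p_tumor), rows summing
# to 1. Any user model exposed through this contract can be explained.

new_predictor <- function(fn) {
  structure(fn, class = c("predictor", "function"))
}

#' Query a predictor on a batch of images
#'
#' Validates the contract: an `n x 2` probability matrix with entries in
#' \[0, 1\] and rows summing to 1 (within 1e-6).
#'
#' @param model A predictor (function: list of image matrices -> n x 2
#'   probability matrix).
#' @param images List of unit-range image matrices (or [gray_image()]s).
#' @return The validated probability matrix.
#' @export
predict_proba <- function(model, images) {
  if (!is.function(model)) stop("`model` must be a function", call. = FALSE)
  if (inherits(images, "gray_image") || is.matrix(images)) {
    images <- list(images)
  }
  images <- lapply(images, as_unit_image)
  p <- model(images)
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) != length(images) ||
      anyNA(p) || min(p) < -1e-9 || max(p) > 1 + 1e-9 ||
      any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("model violated the predictor contract (expected n x 2 probability matrix with rows summing to 1)",
         call. = FALSE)
  }
  dimnames(p) <- NULL
  pmin(pmax(p, 0), 1)
}

#' Oracle predictor, exactly linear in segment presence
#'
#' Builds a deterministic predictor whose tumor probability is
#' `clip(intercept + sum of coefficients of present segments)`, where a
#' segment counts as present iff all of its pixels equal the reference
#' image. Because the response is exactly linear in the presence pattern,
#' the surrogate fit should recover `coefficients` — the explainer's
#' parameter-recovery oracle.
#'
#' @param segmap A [segment_image()] label map.
#' @param coefficients Numeric vector of per-segment weights, named by
#'   segment id (0-based); every name must be a segment of `segmap`.
#' @param intercept Baseline tumor probability.
#' @param reference The unperturbed image the presence test compares to.
#' @return A predictor function.
#' @export
oracle_linear_predictor <- function(segmap, coefficients, intercept,
                                    reference) {
  stopifnot(inherits(segmap, "segment_map"))
  ids <- as.integer(names(coefficients))
  if (anyNA(ids) || !all(ids %in% 0:(segmap$d - 1L))) {
    stop("coefficient names must be segment ids present in `segmap`",
         call. = FALSE)
  }
  ref <- as_unit_image(reference)
  stopifnot(all(dim(ref) == dim(segmap$labels)))
  lab_vec <- as.integer(segmap$labels) + 1L
  d <- segmap$d
  coef_full <- numeric(d)
  coef_full[ids + 1L] <- coefficients
  new_predictor(function(images) {
    p <- vapply(images, function(im) {
      m <- as_unit_image(im)
      changed <- as.numeric(m) != as.numeric(ref)
      altered <- tabulate(lab_vec[changed], d) > 0
      pt <- intercept + sum(coef_full[!altered])
      min(max(pt, 0), 1)
    }, numeric(1))
    cbind(1 - p, p)
  })
}

#' Region mean-intensity mock predictor
#'
#' A stand-in for a trained CNN that has learned a brightness shortcut:
#' `p_tumor = logistic(sharpness * (mean intensity inside region - threshold))`.
#' Occluding bright structures inside `region` (tumor, rim, artifacts)
#' lowers the score, so the explainer assigns them positive importance.
#'
#' @param region A [binary_mask()] defining where the model "looks"
#'   (non-empty).
#' @param threshold Intensity at which the model is maximally uncertain.
#' @param sharpness Slope of the logistic response.
#' @return A predictor function.
#' @export
intensity_predictor <- function(region, threshold = 0.5, sharpness = 10) {
  stopifnot(inherits(region, "binary_mask"))
  idx <- which(mask_pixels(region) == 1L)
  if (length(idx) == 0L) {
    stop("`region` must contain at least one pixel", call. = FALSE)
  }
  new_predictor(function(images) {
    p <- vapply(images, function(im) {
      m <- as_unit_image(im)
      plogis(sharpness * (mean(m[idx]) - threshold))
    }, numeric(1))
    cbind(1 - p, p)
  })
}

#' Brightness-shortcut predictor for a specific image
#'
#' Convenience wrapper around [intensity_predictor()]: the attention
#' region is the set of pixels at or above `cutoff` in the reference
#' image (tumor, rim and artifacts on a phantom), and the logistic
#' midpoint is half that region's mean brightness, so the unperturbed
#' image scores confidently tumor-positive. This is the mock model used
#' by the phantom evaluation harness.
#'
#' @param image Reference image (matrix or [gray_image()], unit range).
#' @param cutoff Brightness cutoff defining the attention region.
#' @param sharpness Logistic slope; moderate values keep the response
#'   graded rather than saturated.
#' @return A predictor function.
#' @export
bright_region_predictor <- function(image, cutoff = 0.7, sharpness = 8) {
  m <- as_unit_image(image)
  region <- binary_mask((m >= cutoff) * 1L, "explanation")
  thr <- mean(m[mask_pixels(region) == 1L]) * 0.5
  intensity_predictor(region, threshold = thr, sharpness = sharpness)
}
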