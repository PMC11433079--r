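# Brain-mask extraction: detector response -> binary raster ->
# morphological closing -> connected components -> largest filled
# component = the brain mask.

#' Build a binary brain mask from an image
#'
#' Runs one of five operators — `laplace`, `sobel` (responses binarized by
#' Otsu on the absolute response), `canny` (already binary edges), `otsu`
#' or `li` (threshold foregrounds) — then closes small gaps
#' morphologically, labels connected components, fills each component's
#' interior holes, and keeps the component with the largest enclosed area.
#' If no component emerges or the mask covers less than `min_fraction` of
#' the frame, the configured fallback is used (`"ones"`: the whole frame,
#' so refinement degrades to the identity; `"empty"`: an all-zero mask).
#'
#' @param img Unit-range grayscale image (matrix or [gray_image()]).
#' @param detector One of `"laplace"`, `"sobel"`, `"canny"`, `"otsu"`,
#'   `"li"`.
#' @param params Named list of detector parameters (`sigma`, `low`,
#'   `high` for canny; `close_size` (3) and `close_iter` (2) for the
#'   closing step).
#' @param min_fraction Smallest acceptable mask/frame area ratio before
#'   the fallback triggers (default 0.05).
#' @param fallback `"ones"` (default) or `"empty"`.
#' @return A `mask_report`: list with `mask` ([binary_mask()], role
#'   brain), `detector`, `contour_count`, `mask_fraction`,
#'   `fallback_used`.
#' @export
build_brain_mask <- function(img, detector = c("otsu", "li", "canny",
                                               "laplace", "sobel"),
                             params = list(), min_fraction = 0.05,
                             fallback = c("ones", "empty")) {
  detector <- match.arg(detector)
  fallback <- match.arg(fallback)
  p <- modifyList(list(sigma = 2, low = 0.1, high = 0.2,
                       close_size = 3L, close_iter = 2L), params)
  m <- as_unit_image(img)
  binary <- tryCatch({
    switch(detector,
      laplace = binarize_response(abs(laplacian_response(m)$response)),
      sobel = binarize_response(sobel_magnitude(m)$response),
      canny = canny_edges(m, sigma = p$sigma, low = p$low,
                          high = p$high)$response,
      otsu = otsu_threshold(m)$binary$response,
      li = li_threshold(m)$binary$response
    )
  }, error = function(e) NULL)  # degenerate input (e.g. constant image)
  finalize_mask(binary, dim(m), detector, p, min_fraction, fallback)
}

# Otsu binarization of a non-negative response raster, rescaled to [0, 1].
binarize_response <- function(resp) {
  mx <- max(resp)
  if (mx == 0) stop("flat response; nothing to binarize", call. = FALSE)
  otsu_threshold(resp / mx)$binary$response
}

# 8-connected component labelling: 4-connected pass, then union of labels
# that touch diagonally (thin diagonal contours must stay one contour).
label8 <- function(x) {
  l4 <- matrix(as.integer(EBImage::bwlabel(x)), nrow(x), ncol(x))
  n <- max(l4)
  if (n <= 1) return(l4)
  h <- nrow(l4); w <- ncol(l4)
  pairs <- rbind(
    cbind(as.integer(l4[-h, -w]), as.integer(l4[-1, -1])),
    cbind(as.integer(l4[-1, -w]), as.integer(l4[-h, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- l4
  out[l4 > 0] <- remap[l4[l4 > 0]]
  out
}

finalize_mask <- function(binary, shape, detector, p, min_fraction,
                          fallback) {
  area <- prod(shape)
  make_fallback <- function(contour_count) {
    px <- if (fallback == "ones") matrix(1L, shape[1], shape[2])
          else matrix(0L, shape[1], shape[2])
    structure(list(mask = binary_mask(px, "brain"), detector = detector,
                   contour_count = contour_count,
                   mask_fraction = sum(px) / area, fallback_used = TRUE),
              class = "mask_report")
  }
  if (is.null(binary) || sum(binary) == 0) return(make_fallback(0L))
  brush <- matrix(1, p$close_size, p$close_size)
  closed <- binary
  for (i in seq_len(p$close_iter)) closed <- EBImage::dilate(closed, brush)
  for (i in seq_len(p$close_iter)) closed <- EBImage::erode(closed, brush)
  lbl <- label8(closed)
  n_comp <- max(lbl)
  if (n_comp == 0) return(make_fallback(0L))
  # fill each contour in isolation: a contour's enclosed area must count
  # interior structure (e.g. a tumor's own edge ring) as inside it
  best_area <- -1L
  mask_px <- NULL
  for (i in seq_len(n_comp)) {
    f <- matrix(as.integer(EBImage::fillHull((lbl == i) * 1L)),
                shape[1], shape[2])
    a_i <- sum(f)
    if (a_i > best_area) {
      best_area <- a_i
      mask_px <- f
    }
  }
  frac <- sum(mask_px) / area
  if (frac < min_fraction) return(make_fallback(n_comp))
  structure(list(mask = binary_mask(mask_px, "brain"), detector = detector,
                 contour_count = n_comp, mask_fraction = frac,
                 fallback_used = FALSE),
            class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat(sprintf("<mask_report %s: %d contour(s), %.1f%% of frame%s>\n",
              x$detector, x$contour_count, 100 * x$mask_fraction,
              if (x$fallback_used) ", FALLBACK" else ""))
  invisible(x)
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask()]s (or 0/1 matrices) of the same shape.
#' @return Dice similarity in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) mask_pixels(a) else a
  pb <- if (inherits(b, "binary_mask")) mask_pixels(b) else b
  stopifnot(all(dim(pa) == dim(pb)))
  denom <- sum(pa) + sum(pb)
  if (denom == 0) return(1)
  2 * sum(pa * pb) / denom
}
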