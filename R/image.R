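#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix (rows = y, columns = x, 0-based
#' pixel indexing at the API level) carrying a declared value range:
#' `"uint8"` (intensities in \[0, 255\]) or `"unit"` (intensities in
#' \[0, 1\]). All pipeline stages after [preprocess()] operate on unit-range
#' images.
#'
#' @param pixels Numeric matrix of intensities.
#' @param value_range `"uint8"` or `"unit"`.
#' @return A `gray_image` object (matrix with attributes).
#' @export
gray_image <- function(pixels, value_range = c("unit", "uint8")) {
  value_range <- match.arg(value_range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains NA intensities", call. = FALSE)
  hi <- if (value_range == "uint8") 255 else 1
  if (min(pixels) < 0 || max(pixels) > hi) {
    stop(sprintf("intensities outside declared %s range [0, %s]",
                 value_range, hi), call. = FALSE)
  }
  structure(pixels, value_range = value_range,
            class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, range=%s, [%.4g, %.4g]>\n",
              nrow(x), ncol(x), attr(x, "value_range"), min(x), max(x)))
  invisible(x)
}

# Strip class/attrs down to a plain matrix.
as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "value_range") <- NULL
  m
}

value_range_of <- function(img) {
  vr <- attr(img, "value_range")
  if (is.null(vr)) "unit" else vr
}

# Coerce any gray_image (or bare matrix) to unit range.
as_unit_image <- function(img) {
  m <- as_pixel_matrix(img)
  if (value_range_of(img) == "uint8") m <- m / 255
  m
}

#' Binary mask container
#'
#' @param pixels Matrix over \{0, 1\} (logical or numeric).
#' @param role One of `"brain"`, `"tumor"`, `"explanation"`.
#' @return A `binary_mask` object (integer matrix with a `role` attribute).
#' @export
binary_mask <- function(pixels, role = c("brain", "tumor", "explanation")) {
  role <- match.arg(role)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  m <- pixels
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("mask values must all be 0 or 1", call. = FALSE)
  }
  structure(m, role = role, class = c("binary_mask", class(m)))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, role=%s, %d foreground px>\n",
              nrow(x), ncol(x), attr(x, "role"), sum(x)))
  invisible(x)
}

mask_pixels <- function(mask) {
  m <- unclass(mask)
  attr(m, "role") <- NULL
  m
}

#' Read a grayscale image from PNG or JPEG
#'
#' Multi-channel inputs are collapsed to one channel by the unweighted mean
#' of the channels. Values are returned on the `uint8` scale (0--255).
#'
#' @param path Path to a PNG or JPEG file.
#' @return A [gray_image()] with `value_range = "uint8"`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file does not exist: %s", path), call. = FALSE)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      stop(sprintf("failed to decode image '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  # EBImage stores (x, y); internal convention is (row = y, col = x).
  gray_image(t(a) * 255, value_range = "uint8")
}

#' Bilinear image resize
#'
#' Separable bilinear resampling with the half-pixel-center convention
#' (destination pixel center `i + 0.5` maps to source coordinate
#' `(i + 0.5) * scale - 0.5`, clamped to the image). Resizing to the source
#' size is the identity.
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Output dimensions (positive integers).
#' @return Numeric matrix of size `out_h x out_w`.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  wmat <- function(n_out, n_in) {
    # two-tap interpolation weights as a dense n_out x n_in matrix
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    fr <- src - lo
    hi <- pmin(lo + 1, n_in - 1)
    w <- matrix(0, n_out, n_in)
    idx <- cbind(seq_len(n_out), lo + 1)
    w[idx] <- w[idx] + (1 - fr)
    idx2 <- cbind(seq_len(n_out), hi + 1)
    w[idx2] <- w[idx2] + fr
    w
  }
  wmat(out_h, nrow(m)) %*% m %*% t(wmat(out_w, ncol(m)))
}

#' Standardize an image to the pipeline's working frame
#'
#' Resizes to `side x side` pixels with bilinear resampling and rescales
#' intensities to the unit interval, the frame all downstream stages
#' (segmentation, explanation, masking, metrics) operate in.
#'
#' @param img A [gray_image()].
#' @param side Target side length in pixels (default 224).
#' @return A unit-range `gray_image` of size `side x side`.
#' @export
preprocess <- function(img, side = 224L) {
  stop_if_not_scalar_number(side, "side")
  if (side <= 0 || side != round(side)) {
    stop("`side` must be a positive integer", call. = FALSE)
  }
  m <- as_unit_image(img)
  out <- resize_bilinear(m, side, side)
  out <- pmin(pmax(out, 0), 1)
  gray_image(out, value_range = "unit")
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Foreground pixels are stored as 255, background as 0; the round-trip is
#' bit-identical.
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path.
#' @param role Mask role to tag on reading.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a [binary_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask_pixels(mask) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, role = c("brain", "tumor", "explanation")) {
  role <- match.arg(role)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  binary_mask((a >= 0.5) * 1L, role = role)
}
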