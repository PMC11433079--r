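#' Polygon tumor annotation
#'
#' Holds the closed polygon outlines drawn around a tumor for one image.
#' Coordinates are in pixel units, `(x, y)` with `x` along columns and `y`
#' along rows, 0-based, matching the VGG Image Annotator (VIA) export.
#'
#' @param polygons List of n x 2 numeric matrices (columns x, y), each with
#'   at least 3 vertices.
#' @param image_id Identifier of the annotated image.
#' @return A `tumor_annotation` object.
#' @export
tumor_annotation <- function(polygons, image_id = "") {
  stopifnot(is.list(polygons))
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p)) {
      stop("each polygon must be a numeric n x 2 matrix with >= 3 vertices",
           call. = FALSE)
    }
  }
  structure(list(polygons = polygons, image_id = as.character(image_id)),
            class = "tumor_annotation")
}

#' @export
print.tumor_annotation <- function(x, ...) {
  cat(sprintf("<tumor_annotation '%s': %d polygon(s)>\n",
              x$image_id, length(x$polygons)))
  invisible(x)
}

# Even-odd (crossing number) test: is the point (px, py) inside the closed
# polygon? Vectorized over points; edges on the boundary follow the usual
# half-open ray convention.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a tumor annotation to a binary mask
#'
#' A pixel belongs to the tumor mask iff its center lies inside at least one
#' polygon under the even-odd rule. Pixel centers are at integer coordinates
#' `(x, y) = (col - 1, row - 1)`.
#'
#' @param ann A [tumor_annotation()].
#' @param shape Integer vector `c(h, w)` of the target raster.
#' @param scale_from Optional `c(h, w)` of the frame the polygons were drawn
#'   in; coordinates are rescaled proportionally onto `shape` (used when
#'   annotations were made on the original image but metrics run on the
#'   preprocessed frame).
#' @return A [binary_mask()] with role `"tumor"`.
#' @export
rasterize_annotation <- function(ann, shape, scale_from = NULL) {
  stopifnot(inherits(ann, "tumor_annotation"), length(shape) == 2L)
  if (length(ann$polygons) == 0L) {
    stop("annotation has no polygons to rasterize", call. = FALSE)
  }
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  grid <- expand.grid(y = seq_len(h) - 1, x = seq_len(w) - 1)
  acc <- rep(FALSE, h * w)
  for (poly in ann$polygons) {
    p <- poly
    if (!is.null(scale_from)) {
      p[, 1] <- p[, 1] * w / scale_from[2]
      p[, 2] <- p[, 2] * h / scale_from[1]
    }
    acc <- acc | point_in_polygon(grid$x, grid$y, p)
  }
  binary_mask(matrix(as.integer(acc), h, w), role = "tumor")
}

#' Read polygon annotations from a VIA JSON export
#'
#' Accepts both the project export (regions under `_via_img_metadata`) and
#' the flat form (top-level map filename -> metadata). Only polygon regions
#' (`shape_attributes$name == "polygon"` with `all_points_x` /
#' `all_points_y`) are kept; other region shapes are skipped with a warning.
#'
#' @param path Path to the VIA JSON file.
#' @return A named list of [tumor_annotation()], one per annotated image.
#' @export
read_via_annotations <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed VIA JSON '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  out <- list()
  for (key in names(doc)) {
    entry <- doc[[key]]
    if (!is.list(entry) || is.null(entry$regions)) next
    fname <- if (!is.null(entry$filename)) entry$filename else key
    polys <- list()
    skipped <- 0L
    for (reg in entry$regions) {
      sa <- reg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) {
        skipped <- skipped + 1L
        next
      }
      xs <- unlist(sa$all_points_x)
      ys <- unlist(sa$all_points_y)
      if (is.null(xs) || is.null(ys) || length(xs) != length(ys)) {
        stop(sprintf("polygon region in '%s' is missing point arrays", fname),
             call. = FALSE)
      }
      polys[[length(polys) + 1L]] <- cbind(x = as.numeric(xs),
                                           y = as.numeric(ys))
    }
    if (skipped > 0L) {
      warning(sprintf("'%s': skipped %d non-polygon region(s)", fname,
                      skipped), call. = FALSE)
    }
    if (length(polys) == 0L) {
      warning(sprintf("'%s': no polygon regions found", fname), call. = FALSE)
    }
    out[[fname]] <- structure(list(polygons = polys, image_id = fname),
                              class = "tumor_annotation")
  }
  out
}

#' Binary-classification confusion metrics
#'
#' Computes accuracy, precision, recall and F1 from the four confusion
#' counts. When a denominator is zero (e.g. no predicted positives), the
#' affected rate is defined as 0 and a warning is emitted.
#'
#' @param tp,tn,fp,fn Non-negative counts; their sum must be positive.
#' @return A `classifier_metrics` list with the counts and the four rates.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all confusion counts are zero; metrics undefined", call. = FALSE)
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  accuracy <- (tp + tn) / sum(counts)
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1),
            class = "classifier_metrics")
}
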