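# Classical edge and threshold operators used to delineate the brain area.
# All operators take unit-range images (plain matrix or gray_image) and
# return an `edge_result`: list(response, detector, binarized).

edge_result <- function(response, detector, binarized) {
  structure(list(response = response, detector = detector,
                 binarized = binarized),
            class = "edge_result")
}

#' @export
print.edge_result <- function(x, ...) {
  cat(sprintf("<edge_result %s %dx%d%s>\n", x$detector,
              nrow(x$response), ncol(x$response),
              if (x$binarized) ", binary" else ""))
  invisible(x)
}

#' 2D correlation with symmetric boundary padding
#'
#' Computes `out(y, x) = sum_ij k(i, j) * img(y + i, x + j)` for an
#' odd-sized kernel, with the image extended by mirror (symmetric)
#' reflection at the borders.
#'
#' @param m Numeric matrix.
#' @param k Odd-dimensioned numeric kernel matrix.
#' @return Matrix of the same size as `m`.
#' @export
convolve2_reflect <- function(m, k) {
  stopifnot(is.matrix(m), is.matrix(k),
            nrow(k) %% 2 == 1, ncol(k) %% 2 == 1)
  pr <- (nrow(k) - 1L) %/% 2L
  pc <- (ncol(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(min(pr, h))), seq_len(h),
            rev(seq_len(h))[seq_len(min(pr, h))])
  cidx <- c(rev(seq_len(min(pc, w))), seq_len(w),
            rev(seq_len(w))[seq_len(min(pc, w))])
  # if pad exceeds image size, recycle the mirrored sequence
  while (length(ridx) < h + 2 * pr) ridx <- c(ridx[1], ridx, ridx[length(ridx)])
  while (length(cidx) < w + 2 * pc) cidx <- c(cidx[1], cidx, cidx[length(cidx)])
  pad <- m[ridx, cidx, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[(i - 1L) + seq_len(h),
                                 (j - 1L) + seq_len(w), drop = FALSE]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with symmetric padding.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  m <- convolve2_reflect(m, matrix(k, ncol = 1))
  convolve2_reflect(m, matrix(k, nrow = 1))
}

#' Laplacian edge response
#'
#' Second-derivative operator: correlation with the 3x3 mask
#' `[[0,1,0],[1,-4,1],[0,1,0]]`, symmetric border padding. Constant and
#' linear-ramp images give a zero interior response.
#'
#' @param img Unit-range grayscale image (matrix or [gray_image()]).
#' @return An `edge_result` with the raw (signed) response.
#' @export
laplacian_response <- function(img) {
  m <- as_unit_image(img)
  k <- matrix(c(0, 1, 0,
                1, -4, 1,
                0, 1, 0), 3, 3, byrow = TRUE)
  edge_result(convolve2_reflect(m, k), "laplace", binarized = FALSE)
}

sobel_kernels <- function() {
  list(
    gx = matrix(c(-1, 0, 1,
                  -2, 0, 2,
                  -1, 0, 1), 3, 3, byrow = TRUE),
    gy = matrix(c(-1, -2, -1,
                   0,  0,  0,
                   1,  2,  1), 3, 3, byrow = TRUE)
  )
}

#' Sobel gradient magnitude
#'
#' Correlates the image with the horizontal and vertical Sobel kernels and
#' returns the gradient magnitude `sqrt(Gx^2 + Gy^2)`. The horizontal
#' component responds to intensity changes along x (columns), the vertical
#' to changes along y (rows).
#'
#' @inheritParams laplacian_response
#' @return An `edge_result` with the non-negative magnitude raster.
#' @export
sobel_magnitude <- function(img) {
  m <- as_unit_image(img)
  k <- sobel_kernels()
  ihor <- convolve2_reflect(m, k$gx)
  iver <- convolve2_reflect(m, k$gy)
  edge_result(sqrt(ihor^2 + iver^2), "sobel", binarized = FALSE)
}

# Internal: Sobel components after optional Gaussian smoothing.
sobel_components <- function(m, sigma = 0) {
  if (sigma > 0) m <- gaussian_blur(m, sigma)
  k <- sobel_kernels()
  list(gx = convolve2_reflect(m, k$gx), gy = convolve2_reflect(m, k$gy))
}

# 8-connected geodesic propagation of `seed` within `mask` (both 0/1
# matrices): the reconstruction used by Canny hysteresis.
propagate_within <- function(seed, mask) {
  brush <- matrix(1, 3, 3)
  cur <- seed & mask
  repeat {
    grown <- (EBImage::dilate(cur * 1, brush) > 0) & mask
    if (sum(grown) == sum(cur)) return(cur * 1L)
    cur <- grown
  }
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis thresholding: pixels above
#' `high` seed edges which extend through 8-connected pixels above `low`.
#' Thresholds are absolute gradient magnitudes (unit-range images give
#' magnitudes roughly in \[0, 4\]), so stronger smoothing weakens gradients
#' and can only prune edges.
#'
#' @inheritParams laplacian_response
#' @param sigma Gaussian smoothing scale in pixels (default 2).
#' @param low,high Hysteresis thresholds on the gradient magnitude;
#'   `low < high` required.
#' @return An `edge_result` with a binary single-pixel-wide edge raster.
#' @export
canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.2) {
  if (low >= high) stop("`low` must be smaller than `high`", call. = FALSE)
  m <- as_unit_image(img)
  g <- sobel_components(m, sigma = sigma)
  mag <- sqrt(g$gx^2 + g$gy^2)
  h <- nrow(m); w <- ncol(m)
  if (max(mag) == 0) {
    return(edge_result(matrix(0L, h, w), "canny", binarized = TRUE))
  }
  # quantize direction into 4 bins: 0 = E/W, 1 = NE/SW, 2 = N/S, 3 = NW/SE
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  dir <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  shift <- function(mm, dy, dx) {
    # value of mm at (y+dy, x+dx), -Inf outside
    out <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys - dy, xs - dx] <- mm[ys, xs]
    out
  }
  # comparison offsets (dy, dx) along the gradient for each direction bin
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(-1, 1))
  nms <- matrix(FALSE, h, w)
  for (b in 0:3) {
    o <- offs[[b + 1]]
    n1 <- shift(mag, o[1], o[2])
    n2 <- shift(mag, -o[1], -o[2])
    sel <- dir == b & mag >= n1 & mag >= n2 & mag > 0
    nms[sel] <- TRUE
  }
  thin <- mag * nms
  strong <- thin >= high
  weak <- thin >= low
  edges <- propagate_within(strong, weak)
  edge_result(edges, "canny", binarized = TRUE)
}

# Exact per-bin statistics on a 256-bin histogram over [lo, hi]: counts and
# intensity sums per bin, so class means are exact, not bin-center
# approximations.
bin_stats <- function(v, lo = 0, hi = 1, nbins = 256L) {
  idx <- pmin(pmax(floor((v - lo) / (hi - lo) * nbins), 0), nbins - 1) + 1L
  counts <- tabulate(idx, nbins)
  full_sums <- numeric(nbins)
  full_sums[sort(unique(idx))] <- as.numeric(rowsum(v, idx)[, 1])
  list(counts = counts, sums = full_sums,
       edges = lo + (0:nbins) / nbins * (hi - lo))
}

#' Otsu's threshold
#'
#' Selects, over 256 uniform histogram bins on \[0, 1\], the threshold
#' maximizing the between-class variance
#' `V(t) = pB(t) * pF(t) * (muB(t) - muF(t))^2`, where the background holds
#' intensities below `t` and the foreground intensities at or above `t`.
#' Class proportions and means are computed exactly from the pixel values.
#' Ties are broken toward the lowest threshold.
#'
#' @inheritParams laplacian_response
#' @return List with `thr` (the selected threshold) and `binary`, an
#'   `edge_result` holding the thresholded image (`I >= thr`).
#' @export
otsu_threshold <- function(img) {
  m <- as_unit_image(img)
  v <- as.numeric(m)
  if (length(unique(v)) < 2L) {
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  }
  bs <- bin_stats(v)
  n <- length(v)
  cum_n <- cumsum(bs$counts)
  cum_s <- cumsum(bs$sums)
  # candidate k: background = bins 1..k-1, i.e. thr = edge k ( = (k-1)/256 )
  best_v <- -1; best_k <- NA_integer_
  for (k in 2:256) {
    nb <- cum_n[k - 1]; nf <- n - nb
    if (nb == 0 || nf == 0) next
    mub <- cum_s[k - 1] / nb
    muf <- (cum_s[256] - cum_s[k - 1]) / nf
    vv <- (nb / n) * (nf / n) * (mub - muf)^2
    if (vv > best_v + 1e-15) {
      best_v <- vv
      best_k <- k
    }
  }
  thr <- bs$edges[best_k]
  edge <- edge_result((m >= thr) * 1L, "otsu", binarized = TRUE)
  list(thr = thr, binary = edge)
}

# Li cross-entropy objective at threshold t on pixel vector v:
# -(sum of background intensities) * log(muB) - (sum of foreground) * log(muF),
# the threshold-dependent part of the cross-entropy between each region and
# its mean. Means are floored at a small epsilon so exact-zero backgrounds
# remain comparable.
li_objective <- function(v, thr, eps = 1e-12) {
  b <- v[v < thr]; f <- v[v >= thr]
  if (length(b) == 0 || length(f) == 0) return(Inf)
  mub <- max(mean(b), eps)
  muf <- max(mean(f), eps)
  -(sum(b) * log(mub) + sum(f) * log(muf))
}

#' Li's minimum cross-entropy threshold
#'
#' Minimizes `HF(thr) + HB(thr)`, the cross-entropy between each class
#' (background below `thr`, foreground at or above it) and that class's
#' mean intensity, searching all 256 candidate thresholds of a uniform
#' histogram on \[0, 1\]. Class sums are computed exactly from the pixel
#' values; the classic fixed-point iteration can stall in shallow local
#' minima on near-flat histograms, so the search here is exhaustive.
#'
#' @inheritParams laplacian_response
#' @return List with `thr` and `binary` (an `edge_result`, `I >= thr`).
#' @export
li_threshold <- function(img) {
  m <- as_unit_image(img)
  v <- as.numeric(m)
  if (length(unique(v)) < 2L) {
    stop("Li threshold undefined for a constant image", call. = FALSE)
  }
  eps <- 1e-12
  bs <- bin_stats(v)
  cum_n <- cumsum(bs$counts)
  cum_s <- cumsum(bs$sums)
  n <- length(v); s_tot <- cum_s[256]
  best_obj <- Inf; best_k <- NA_integer_
  for (k in 2:256) {
    nb <- cum_n[k - 1]; nf <- n - nb
    if (nb == 0 || nf == 0) next
    sb <- cum_s[k - 1]; sf <- s_tot - sb
    mub <- max(sb / nb, eps)
    muf <- max(sf / nf, eps)
    obj <- -(sb * log(mub) + sf * log(muf))
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best_k <- k
    }
  }
  thr <- bs$edges[best_k]
  edge <- edge_result((m >= thr) * 1L, "li", binarized = TRUE)
  list(thr = thr, binary = edge)
}
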