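# Superpixel segmentation. Three grayscale oversegmenters are provided:
# SLIC (local k-means in joint intensity/space), quickshift (mode seeking
# on a kernel density in joint feature space), and Felzenszwalb's
# graph-based merging. Labels are always relabeled to 0..d-1 and every
# pixel belongs to exactly one segment.

#' Superpixel segmentation of a grayscale image
#'
#' @param img Unit-range grayscale image (matrix or [gray_image()]).
#' @param algorithm `"slic"`, `"quickshift"`, or `"felzenszwalb"`.
#' @param params Named list of algorithm parameters overriding the
#'   defaults: SLIC — `n_segments` (50), `compactness` (10), `max_iter`
#'   (10); quickshift — `kernel_size` (4), `max_dist` (200), `ratio`
#'   (0.2); felzenszwalb — `scale` (100), `sigma` (0.8), `min_size` (50).
#' @param seed Seed for the density tie-break noise in quickshift (the
#'   other two algorithms are deterministic).
#' @return A `segment_map`: list with `labels` (integer matrix, 0-based),
#'   `d` (number of segments), `algorithm`, `params`.
#' @export
segment_image <- function(img, algorithm = c("slic", "quickshift",
                                             "felzenszwalb"),
                          params = list(), seed = 0L) {
  algorithm <- match.arg(algorithm)
  m <- as_unit_image(img)
  labels <- switch(algorithm,
    slic = slic_labels(m, params),
    quickshift = quickshift_labels(m, params, seed),
    felzenszwalb = felzenszwalb_labels(m, params)
  )
  labels <- relabel_consecutive(labels)
  structure(list(labels = labels, d = max(labels) + 1L,
                 algorithm = algorithm, params = params),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map %s: %d segments over %dx%d>\n", x$algorithm,
              x$d, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  out <- matrix(match(as.integer(labels), u) - 1L,
                nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

#' Pixel count of every segment
#'
#' @param segmap A `segment_map`.
#' @return Integer vector of length `d` (segment `i`'s size at index
#'   `i + 1`).
#' @export
segment_sizes <- function(segmap) {
  stopifnot(inherits(segmap, "segment_map"))
  tabulate(as.integer(segmap$labels) + 1L, segmap$d)
}

# ---- SLIC ------------------------------------------------------------

slic_labels <- function(m, params) {
  p <- modifyList(list(n_segments = 50L, compactness = 10, max_iter = 10L),
                  params)
  h <- nrow(m); w <- ncol(m)
  k <- max(1L, as.integer(p$n_segments))
  s_step <- sqrt(h * w / k)
  # initial centers on a regular grid
  ny <- max(1L, round(h / s_step)); nx <- max(1L, ceiling(k / ny))
  cy <- (seq_len(ny) - 0.5) * h / ny
  cx <- (seq_len(nx) - 0.5) * w / nx
  centers <- expand.grid(y = cy, x = cx)
  centers$int <- m[cbind(pmax(1, round(centers$y)),
                         pmax(1, round(centers$x)))]
  ci <- 100 * m  # intensity on a Lab-like 0-100 scale
  mres <- p$compactness
  yy <- matrix(seq_len(h), h, w); xx <- t(matrix(seq_len(w), w, h))
  lab <- matrix(1L, h, w)
  for (iter in seq_len(p$max_iter)) {
    dist <- matrix(Inf, h, w)
    for (j in seq_len(nrow(centers))) {
      y0 <- max(1L, floor(centers$y[j] - 2 * s_step))
      y1 <- min(h, ceiling(centers$y[j] + 2 * s_step))
      x0 <- max(1L, floor(centers$x[j] - 2 * s_step))
      x1 <- min(w, ceiling(centers$x[j] + 2 * s_step))
      dy <- yy[y0:y1, x0:x1] - centers$y[j]
      dx <- xx[y0:y1, x0:x1] - centers$x[j]
      dc <- ci[y0:y1, x0:x1] - 100 * centers$int[j]
      d2 <- dc^2 + (dy^2 + dx^2) * (mres / s_step)^2
      win <- dist[y0:y1, x0:x1]
      upd <- d2 < win
      win[upd] <- d2[upd]
      dist[y0:y1, x0:x1] <- win
      labwin <- lab[y0:y1, x0:x1]
      labwin[upd] <- j
      lab[y0:y1, x0:x1] <- labwin
    }
    # recompute centers
    for (j in seq_len(nrow(centers))) {
      sel <- lab == j
      if (!any(sel)) next
      centers$y[j] <- mean(yy[sel])
      centers$x[j] <- mean(xx[sel])
      centers$int[j] <- mean(m[sel])
    }
  }
  enforce_connectivity(lab)
}

# Split each label into 4-connected components, keep the largest per
# label, and absorb the orphans into an adjacent segment.
enforce_connectivity <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  comp <- matrix(0L, h, w)
  offset <- 0L
  for (v in sort(unique(as.integer(lab)))) {
    cc <- EBImage::bwlabel((lab == v) * 1)
    cc <- matrix(as.integer(cc), h, w)
    comp[cc > 0L] <- cc[cc > 0L] + offset
    offset <- offset + max(cc)
  }
  sizes <- tabulate(comp, offset)
  # main component per label value = largest
  main <- rep(FALSE, offset)
  for (v in sort(unique(as.integer(lab)))) {
    ids <- sort(unique(comp[lab == v]))
    main[ids[which.max(sizes[ids])]] <- TRUE
  }
  # absorb orphan components into a 4-neighbor segment, smallest first
  orphans <- which(!main)
  orphans <- orphans[order(sizes[orphans])]
  for (oc in orphans) {
    sel <- comp == oc
    if (!any(sel)) next
    ring <- (EBImage::dilate(sel * 1, matrix(1, 3, 3)) > 0) & !sel
    cand <- lab[ring & comp > 0 & matrix(main[pmax(comp, 1L)], h, w)]
    if (length(cand) == 0L) cand <- lab[ring]
    if (length(cand) == 0L) next
    tgt <- as.integer(names(which.max(table(cand))))
    lab[sel] <- tgt
  }
  lab
}

# ---- Quickshift ------------------------------------------------------

quickshift_labels <- function(m, params, seed = 0L) {
  p <- modifyList(list(kernel_size = 4, max_dist = 200, ratio = 0.2),
                  params)
  h <- nrow(m); w <- ncol(m)
  sig <- p$kernel_size
  feat <- 100 * p$ratio * m  # intensity scaled against pixel distances
  wrad <- max(1L, ceiling(2 * sig))
  offs <- expand.grid(dy = -wrad:wrad, dx = -wrad:wrad)
  offs <- offs[offs$dy^2 + offs$dx^2 <= wrad^2 &
                 !(offs$dy == 0 & offs$dx == 0), ]
  shifted <- function(mm, dy, dx, fill) {
    out <- matrix(fill, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys - dy, xs - dx] <- mm[ys, xs]
    out
  }
  # kernel density in joint (y, x, feat) space
  dens <- matrix(0, h, w)
  for (r in seq_len(nrow(offs))) {
    dy <- offs$dy[r]; dx <- offs$dx[r]
    df <- shifted(feat, dy, dx, NA) - feat
    d2 <- dy^2 + dx^2 + df^2
    contrib <- exp(-d2 / (2 * sig^2))
    contrib[is.na(contrib)] <- 0
    dens <- dens + contrib
  }
  # tiny seeded jitter breaks the ties of flat regions
  dens <- dens + with_seed(seed, matrix(runif(h * w, 0, 1e-6), h, w))
  # parent: nearest neighbor (joint distance) with strictly higher density
  best_d2 <- matrix(Inf, h, w)
  parent_dy <- matrix(0L, h, w)
  parent_dx <- matrix(0L, h, w)
  for (r in seq_len(nrow(offs))) {
    dy <- offs$dy[r]; dx <- offs$dx[r]
    nb_dens <- shifted(dens, dy, dx, -Inf)
    df <- shifted(feat, dy, dx, NA) - feat
    d2 <- dy^2 + dx^2 + df^2
    ok <- nb_dens > dens & !is.na(d2) & d2 < best_d2 &
      d2 <= p$max_dist^2
    best_d2[ok] <- d2[ok]
    parent_dy[ok] <- dy
    parent_dx[ok] <- dx
  }
  idx <- matrix(seq_len(h * w), h, w)
  py <- row(idx) + parent_dy
  px <- col(idx) + parent_dx
  parent <- as.integer((px - 1L) * h + py)
  # follow parents to the roots
  lab <- seq_len(h * w)
  repeat {
    nxt <- parent[lab]
    if (all(nxt == lab)) break
    lab <- nxt
  }
  matrix(as.integer(lab), h, w)
}

# ---- Felzenszwalb ----------------------------------------------------

felzenszwalb_labels <- function(m, params) {
  p <- modifyList(list(scale = 100, sigma = 0.8, min_size = 50L), params)
  h <- nrow(m); w <- ncol(m)
  sm <- if (p$sigma > 0) gaussian_blur(m, p$sigma) else m
  g <- 255 * sm  # classic 0-255 intensity scale for edge weights
  idx <- matrix(seq_len(h * w), h, w)
  edge_set <- function(dy, dx) {
    ys <- 1:(h - max(dy, 0)); xs <- 1:(w - max(dx, 0))
    ys <- ys[ys + dy >= 1]; xs <- xs[xs + dx >= 1]
    a <- idx[ys, xs]
    b <- idx[ys + dy, xs + dx]
    cbind(as.integer(a), as.integer(b),
          abs(g[cbind(rep(ys, length(xs)), rep(xs, each = length(ys)))] -
              g[cbind(rep(ys + dy, length(xs)),
                      rep(xs + dx, each = length(ys)))]))
  }
  edges <- rbind(edge_set(1L, 0L), edge_set(0L, 1L),
                 edge_set(1L, 1L), edge_set(-1L, 1L))
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  n <- h * w
  parent <- seq_len(n)
  size <- rep(1L, n)
  internal <- numeric(n)  # max internal edge weight per component
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  k <- p$scale
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a == b) next
    wgt <- edges[e, 3]
    if (wgt <= min(internal[a] + k / size[a],
                   internal[b] + k / size[b])) {
      parent[b] <- a
      size[a] <- size[a] + size[b]
      internal[a] <- max(internal[a], wgt)
    }
  }
  # merge components below min_size along the sorted edges
  if (p$min_size > 1) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) next
      if (size[a] < p$min_size || size[b] < p$min_size) {
        parent[b] <- a
        size[a] <- size[a] + size[b]
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  matrix(as.integer(roots), h, w)
}
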