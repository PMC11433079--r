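# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as naive scalar code, separate from the
# vectorized implementations they check.

# scalar even-odd point-in-polygon over every pixel center
oracle_rasterize <- function(polys, h, w) {
  inside_one <- function(px, py, poly) {
    n <- nrow(poly); inside <- FALSE; j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      for (p in polys) {
        if (inside_one(c - 1, r - 1, p)) {
          out[r, c] <- 1L
          break
        }
      }
    }
  }
  out
}

# scalar bilinear resampler with the half-pixel-center convention
oracle_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, out_h, out_w)
  for (r in seq_len(out_h)) {
    for (c in seq_len(out_w)) {
      sy <- min(max((r - 0.5) * h / out_h - 0.5, 0), h - 1)
      sx <- min(max((c - 0.5) * w / out_w - 0.5, 0), w - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      fy <- sy - y0; fx <- sx - x0
      out[r, c] <- (1 - fy) * ((1 - fx) * m[y0 + 1, x0 + 1] +
                                 fx * m[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * m[y1 + 1, x0 + 1] + fx * m[y1 + 1, x1 + 1])
    }
  }
  out
}

# direct correlation with symmetric padding, scalar loops
oracle_convolve <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  pr <- (nrow(k) - 1) %/% 2; pc <- (ncol(k) - 1) %/% 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (i in seq_len(nrow(k))) {
        for (j in seq_len(ncol(k))) {
          acc <- acc + k[i, j] * m[reflect(r + i - 1 - pr, h),
                                   reflect(c + j - 1 - pc, w)]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# exhaustive 256-bin Otsu: recompute class stats from raw pixels at every
# candidate threshold
oracle_otsu <- function(v) {
  best_v <- -1; best_thr <- NA
  n <- length(v)
  for (k in 2:256) {
    thr <- (k - 1) / 256
    b <- v[v < thr]; f <- v[v >= thr]
    if (length(b) == 0 || length(f) == 0) next
    vv <- (length(b) / n) * (length(f) / n) * (mean(b) - mean(f))^2
    if (vv > best_v + 1e-15) {
      best_v <- vv
      best_thr <- thr
    }
  }
  best_thr
}

# exhaustive 256-bin minimization of the Li cross-entropy objective
oracle_li <- function(v) {
  obj <- function(thr) {
    b <- v[v < thr]; f <- v[v >= thr]
    if (length(b) == 0 || length(f) == 0) return(Inf)
    -(sum(b) * log(max(mean(b), 1e-12)) +
        sum(f) * log(max(mean(f), 1e-12)))
  }
  thrs <- (1:255) / 256
  vals <- vapply(thrs, obj, numeric(1))
  thrs[which.min(vals)]
}

# scalar pixel-count coverage
oracle_coverage <- function(expl, ref) {
  inter <- 0L; denom <- 0L
  for (r in seq_len(nrow(ref))) {
    for (c in seq_len(ncol(ref))) {
      if (ref[r, c] == 1L) {
        denom <- denom + 1L
        if (expl[r, c] == 1L) inter <- inter + 1L
      }
    }
  }
  100 * inter / denom
}

# weighted ridge fit via the data-augmentation route (independent of the
# normal-equations solver in the package): rows scaled by sqrt(weight),
# ridge as sqrt(lambda) pseudo-observations on the slopes only
oracle_ridge <- function(x, y, wts, lambda) {
  a <- cbind(1, x)
  aw <- a * sqrt(wts)
  yw <- y * sqrt(wts)
  d <- ncol(x)
  aug <- cbind(0, diag(sqrt(lambda), d))
  fit <- qr.solve(rbind(aw, aug), c(yw, numeric(d)))
  list(intercept = fit[1], weights = fit[-1])
}

# small segment map: k vertical bands over an h x w frame
band_segmap <- function(h, w, k) {
  labels <- matrix(rep(floor((seq_len(w) - 1) * k / w), each = h), h, w)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, d = k, algorithm = "slic",
                 params = list()),
            class = "segment_map")
}

tiny_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(side = 96, brain_axes = c(36, 28), tumor_radius = 7,
         n_artifacts = 1L),
    list(...)
  )
  do.call(phantom_spec, args)
}
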