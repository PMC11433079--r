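# Perturbation-based local explanation: mask random subsets of segments,
# query the model, and fit a weighted ridge surrogate whose coefficients
# are the per-segment importances.

#' Sample a set of segment-presence patterns
#'
#' Row 1 is the all-ones pattern (the unperturbed image); the remaining
#' rows keep each segment independently with probability 1/2.
#'
#' @param d Number of segments.
#' @param n_samples Number of patterns (>= 2; default 1000).
#' @param seed Seed for reproducibility.
#' @return A `perturbation_set`: list with `presence` (n_samples x d 0/1
#'   matrix), `n_samples`, `seed`.
#' @export
sample_perturbations <- function(d, n_samples = 1000L, seed = 1L) {
  stopifnot(d >= 1)
  if (n_samples < 2) {
    stop("`n_samples` must be at least 2 (the original plus one perturbation)",
         call. = FALSE)
  }
  pres <- with_seed(seed, {
    m <- matrix(rbinom((n_samples - 1L) * d, 1L, 0.5), n_samples - 1L, d)
    rbind(rep(1L, d), m)
  })
  structure(list(presence = pres, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "perturbation_set")
}

#' Apply one presence pattern to an image
#'
#' Kept segments are untouched; dropped segments are filled with either
#' their own mean intensity (`"segment_mean"`, the default occlusion for
#' this explainer family) or zeros.
#'
#' @param img Unit-range image (matrix or [gray_image()]).
#' @param segmap A [segment_image()] label map of the same shape.
#' @param row 0/1 vector of length `d`; `row[i+1] == 1` keeps segment `i`.
#' @param fill `"segment_mean"` or `"zero"`.
#' @return The perturbed image matrix.
#' @export
apply_perturbation <- function(img, segmap, row,
                               fill = c("segment_mean", "zero")) {
  fill <- match.arg(fill)
  m <- as_unit_image(img)
  stopifnot(inherits(segmap, "segment_map"))
  if (!all(dim(m) == dim(segmap$labels))) {
    stop("image and segment map shapes differ", call. = FALSE)
  }
  if (length(row) != segmap$d) {
    stop("presence row length must equal the number of segments",
         call. = FALSE)
  }
  lab1 <- as.integer(segmap$labels) + 1L
  fillvals <- if (fill == "segment_mean") {
    as.numeric(tapply(as.numeric(m), lab1, mean))[lab1]
  } else 0
  dropped <- row[lab1] == 0
  out <- m
  out[dropped] <- if (length(fillvals) > 1) fillvals[dropped] else 0
  out
}

# cosine distance of each presence row to the all-ones row
cosine_dist_to_ones <- function(presence) {
  mfrac <- rowMeans(presence)
  sim <- sqrt(mfrac)  # <row, 1>/(||row|| ||1||) = m/sqrt(m d) /... = sqrt(m/d)
  sim[mfrac == 0] <- 0
  1 - sim
}

#' Fit the weighted ridge surrogate
#'
#' Regresses the model responses on the binary presence matrix by
#' ridge-penalized weighted least squares. Sample weights follow an
#' exponential kernel on the cosine distance to the unperturbed pattern,
#' `exp(-dist^2 / kernel_width^2)`; the intercept is fitted unpenalized
#' and not reported. The coefficients are the per-segment importances.
#'
#' @param pset A [sample_perturbations()] result.
#' @param responses Tumor-class probability for each presence row, in
#'   \[0, 1\].
#' @param kernel_width Kernel width for the locality weights (default
#'   0.25).
#' @param ridge Ridge penalty on the segment coefficients (default 1).
#' @param explained_class Class the responses refer to (default 1).
#' @return A `lime_heatmap`: list with `weights` (numeric named by segment
#'   id), `intercept`, `explained_class`.
#' @export
fit_surrogate <- function(pset, responses, kernel_width = 0.25, ridge = 1,
                          explained_class = 1L) {
  stopifnot(inherits(pset, "perturbation_set"))
  x <- pset$presence
  if (length(responses) != nrow(x)) {
    stop("`responses` length must match the number of presence rows",
         call. = FALSE)
  }
  d <- ncol(x)
  wts <- exp(-cosine_dist_to_ones(x)^2 / kernel_width^2)
  a <- cbind(1, x)
  pen <- diag(c(0, rep(ridge, d)), d + 1L)
  xtwx <- crossprod(a, wts * a) + pen
  xtwy <- crossprod(a, wts * responses)
  beta <- tryCatch(solve(xtwx, xtwy), error = function(e) {
    stop("surrogate fit is singular (presence rows carry no variation); increase n_samples",
         call. = FALSE)
  })
  weights <- as.numeric(beta[-1])
  names(weights) <- as.character(seq_len(d) - 1L)
  structure(list(weights = weights, intercept = as.numeric(beta[1]),
                 explained_class = as.integer(explained_class)),
            class = "lime_heatmap")
}

#' @export
print.lime_heatmap <- function(x, ...) {
  top <- utils::head(sort(x$weights, decreasing = TRUE), 5)
  cat(sprintf("<lime_heatmap: %d segments, class %d; top: %s>\n",
              length(x$weights), x$explained_class,
              paste(sprintf("%s=%.3g", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Explain one image
#'
#' Full explanation pipeline: segment the image, sample presence patterns,
#' occlude, query the model in batches, and fit the surrogate. By default
#' only tumor-positive predictions (`p_tumor >= 0.5`) are explained,
#' mirroring how the method is used in practice.
#'
#' @inheritParams segment_image
#' @param model A predictor (see [predict_proba()]).
#' @param n_samples Number of perturbations (default 1000).
#' @param seed Seed driving the presence sampling.
#' @param fill Occlusion fill policy (see [apply_perturbation()]).
#' @param kernel_width,ridge Surrogate parameters (see [fit_surrogate()]).
#' @param require_positive Error if the model does not classify `img` as
#'   tumor-positive; set `FALSE` to explain class 0 scores for testing.
#' @param segmap Optional precomputed [segment_image()] map (skips
#'   segmentation).
#' @param batch_size Images per model call.
#' @return A `lime_heatmap` with attribute `"segmap"` holding the label
#'   map used.
#' @export
explain_image <- function(img, model, algorithm = "slic", params = list(),
                          n_samples = 1000L, seed = 1L,
                          fill = c("segment_mean", "zero"),
                          kernel_width = 0.25, ridge = 1,
                          require_positive = TRUE, segmap = NULL,
                          batch_size = 200L) {
  fill <- match.arg(fill)
  m <- as_unit_image(img)
  p0 <- predict_proba(model, list(m))[1, 2]
  if (require_positive && p0 < 0.5) {
    stop(sprintf("model scores this image tumor-negative (p_tumor = %.3f); only positive predictions are explained",
                 p0), call. = FALSE)
  }
  if (is.null(segmap)) {
    segmap <- segment_image(m, algorithm = algorithm, params = params,
                            seed = seed)
  }
  pset <- sample_perturbations(segmap$d, n_samples = n_samples, seed = seed)
  lab1 <- as.integer(segmap$labels) + 1L
  fillvals <- if (fill == "segment_mean") {
    as.numeric(tapply(as.numeric(m), lab1, mean))[lab1]
  } else rep(0, length(lab1))
  responses <- numeric(pset$n_samples)
  i <- 1L
  while (i <= pset$n_samples) {
    j <- min(i + batch_size - 1L, pset$n_samples)
    batch <- lapply(i:j, function(r) {
      row <- pset$presence[r, ]
      dropped <- row[lab1] == 0
      out <- m
      out[dropped] <- fillvals[dropped]
      out
    })
    responses[i:j] <- predict_proba(model, batch)[, 2]
    i <- j + 1L
  }
  hm <- fit_surrogate(pset, responses, kernel_width = kernel_width,
                      ridge = ridge, explained_class = 1L)
  attr(hm, "segmap") <- segmap
  hm
}

#' Select the n most important segments
#'
#' Segments with strictly positive weight, ordered by decreasing weight
#' with ties broken by ascending segment id, truncated to `n`. Fewer than
#' `n` ids are returned when fewer segments have positive weight.
#'
#' @param h A `lime_heatmap` or `refined_heatmap`.
#' @param n Maximum number of segments (>= 1).
#' @return Integer vector of segment ids (possibly empty).
#' @export
top_n_segments <- function(h, n) {
  stopifnot(n >= 1)
  w <- h$weights
  ids <- as.integer(names(w))
  keep <- w > 0
  ids <- ids[keep]; w <- w[keep]
  ord <- order(-w, ids)
  utils::head(ids[ord], n)
}

#' Serialize / deserialize a heatmap as JSON
#'
#' @param h A `lime_heatmap`.
#' @param path JSON path.
#' @return `write_heatmap_json` returns `path` invisibly;
#'   `read_heatmap_json` returns a `lime_heatmap`.
#' @export
write_heatmap_json <- function(h, path) {
  jsonlite::write_json(list(weights = as.list(h$weights),
                            intercept = h$intercept,
                            explained_class = h$explained_class),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heatmap_json
#' @export
read_heatmap_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  w <- unlist(doc$weights)
  structure(list(weights = w, intercept = doc$intercept,
                 explained_class = as.integer(doc$explained_class)),
            class = "lime_heatmap")
}

#' Write / read a segment label map as TSV
#'
#' Plain-text serialization of the integer label raster (one row per image
#' row, tab-separated), with a `# algorithm=` header line.
#'
#' @param segmap A `segment_map`.
#' @param path Output path.
#' @return `write_segments_tsv` returns `path` invisibly;
#'   `read_segments_tsv` returns a `segment_map`.
#' @export
write_segments_tsv <- function(segmap, path) {
  stopifnot(inherits(segmap, "segment_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# algorithm=%s", segmap$algorithm), con)
  utils::write.table(segmap$labels, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  alg <- sub("^# algorithm=", "", header)
  labels <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, d = max(labels) + 1L,
                 algorithm = alg, params = list()),
            class = "segment_map")
}
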