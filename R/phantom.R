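#' Synthetic brain-phantom specification
#'
#' Describes one synthetic, MRI-like grayscale slice: a filled brain
#' ellipse with Gaussian texture, a bright skull-like rim hugging the
#' ellipse, optional bright background artifact discs (the out-of-brain
#' distractors that attract spurious explanation importance), and an
#' optional bright tumor disc strictly inside the brain.
#'
#' @param side Image side in pixels (default 224, the working frame).
#' @param brain_axes Semi-axes `c(a, b)` of the brain ellipse, in pixels
#'   (`a` along rows/y, `b` along columns/x).
#' @param brain_center Center `c(y, x)` of the brain ellipse (0-based).
#' @param brain_intensity Mean brain tissue intensity in (0, 1).
#' @param rim_present Whether the skull-like rim ring is drawn.
#' @param rim_intensity Intensity of the ~2-pixel skull rim in (0, 1].
#' @param tumor_present Whether a tumor disc is drawn.
#' @param tumor_center Center `c(y, x)` of the tumor disc.
#' @param tumor_radius Tumor disc radius in pixels.
#' @param tumor_intensity Tumor intensity in (0, 1].
#' @param n_artifacts Number of bright background artifact discs.
#' @param artifact_radius Radius of the artifact discs in pixels; sized
#'   like a typical tumor so they genuinely compete for importance.
#' @param artifact_intensity Intensity of the artifact discs.
#' @param noise_sd Gaussian texture SD inside the brain; the background
#'   uses `noise_sd / 2`.
#' @param seed Integer seed making the sample a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(side = 224L,
                         brain_axes = c(85, 65),
                         brain_center = NULL,
                         brain_intensity = 0.45,
                         rim_present = TRUE,
                         rim_intensity = 0.9,
                         tumor_present = TRUE,
                         tumor_center = NULL,
                         tumor_radius = 14,
                         tumor_intensity = 0.85,
                         n_artifacts = 2L,
                         artifact_radius = 9,
                         artifact_intensity = 0.9,
                         noise_sd = 0.03,
                         seed = 1L) {
  if (is.null(brain_center)) brain_center <- c(side, side) / 2
  if (is.null(tumor_center)) {
    tumor_center <- brain_center + c(-0.35, 0.4) * brain_axes
  }
  spec <- structure(list(
    side = as.integer(side), brain_axes = brain_axes,
    brain_center = brain_center, brain_intensity = brain_intensity,
    rim_present = isTRUE(rim_present), rim_intensity = rim_intensity,
    tumor_present = isTRUE(tumor_present),
    tumor_center = tumor_center, tumor_radius = tumor_radius,
    tumor_intensity = tumor_intensity,
    n_artifacts = as.integer(n_artifacts),
    artifact_radius = artifact_radius,
    artifact_intensity = artifact_intensity,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (side < 16) stop("`side` too small for a phantom", call. = FALSE)
    for (v in c(brain_intensity, rim_intensity, tumor_intensity)) {
      if (v <= 0 || v > 1) {
        stop("intensities must lie in (0, 1]", call. = FALSE)
      }
    }
    if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
    if (tumor_present) {
      # tumor disc must sit entirely inside the brain ellipse: the scaled
      # center distance plus the radius margin must stay below 1
      rho <- sqrt(sum(((tumor_center - brain_center) / brain_axes)^2))
      margin <- tumor_radius / min(brain_axes)
      if (rho + margin >= 1) {
        stop("tumor disc does not lie entirely inside the brain ellipse",
             call. = FALSE)
      }
    }
  })
  invisible(spec)
}

# normalized elliptical radius of every pixel (0-based centers)
ellipse_rho <- function(side, center, axes) {
  y <- matrix(seq_len(side) - 1, side, side)
  x <- t(y)
  sqrt(((y - center[1]) / axes[1])^2 + ((x - center[2]) / axes[2])^2)
}

disc_mask <- function(side, center, radius) {
  y <- matrix(seq_len(side) - 1, side, side)
  x <- t(y)
  (y - center[1])^2 + (x - center[2])^2 <= radius^2
}

#' Generate one synthetic brain phantom
#'
#' Renders the spec into a unit-range image plus ground-truth brain and
#' tumor masks. Noiseless specs produce exactly piecewise-constant images,
#' so any threshold between background and brain intensity recovers the
#' brain truth; this anchors the brain-mask quality tests.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_sample`: list with `image` ([gray_image()], unit
#'   range), `brain_truth` and `tumor_truth` ([binary_mask()]), binary
#'   `label` (1 iff the tumor mask is non-empty), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  s <- spec$side
  rho <- ellipse_rho(s, spec$brain_center, spec$brain_axes)
  brain <- rho <= 1
  rim_width <- 2.5 / min(spec$brain_axes)
  rim <- spec$rim_present & rho > 1 & rho <= 1 + rim_width
  img <- matrix(0, s, s)
  img[brain] <- spec$brain_intensity
  img[rim] <- spec$rim_intensity
  tumor <- matrix(FALSE, s, s)
  if (spec$tumor_present && spec$tumor_radius > 0) {
    tumor <- disc_mask(s, spec$tumor_center, spec$tumor_radius)
    img[tumor] <- spec$tumor_intensity
  }
  if (spec$n_artifacts > 0) {
    # deterministic artifact placement: corners in fixed order, jittered
    corners <- list(c(0.12, 0.12), c(0.12, 0.88), c(0.88, 0.88),
                    c(0.88, 0.12))
    with_seed(spec$seed * 7L + 13L, {
      for (i in seq_len(spec$n_artifacts)) {
        ctr <- corners[[(i - 1L) %% 4L + 1L]] * (s - 1) +
          round(runif(2, -4, 4))
        art <- disc_mask(s, ctr, spec$artifact_radius) &
          rho > 1 + rim_width + 4 / min(spec$brain_axes)
        img[art] <- spec$artifact_intensity
      }
    })
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      noise <- matrix(rnorm(s * s, 0, spec$noise_sd / 2), s, s)
      noise[brain] <- rnorm(sum(brain), 0, spec$noise_sd)
      img <- pmin(pmax(img + noise, 0), 1)
    })
  }
  structure(list(
    image = gray_image(img, "unit"),
    brain_truth = binary_mask(brain * 1L, "brain"),
    tumor_truth = binary_mask(tumor * 1L, "tumor"),
    label = as.integer(sum(tumor) > 0),
    spec = spec
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample %dx%d, label=%d, brain=%d px, tumor=%d px>\n",
              x$spec$side, x$spec$side, x$label, sum(x$brain_truth),
              sum(x$tumor_truth)))
  invisible(x)
}

#' Generate a reproducible batch of phantoms
#'
#' Exactly `round(n * tumor_fraction)` samples carry a tumor; which
#' positions are positive, and the per-sample geometry jitter, derive
#' deterministically from `seed` via per-sample counters.
#'
#' @param n Number of samples.
#' @param base A [phantom_spec()] serving as the template.
#' @param tumor_fraction Fraction of tumor-positive samples in \[0, 1\].
#' @param seed Batch seed.
#' @return List of `phantom_sample`s with names `phantom_001`, ...
#' @export
generate_batch <- function(n, base = phantom_spec(), tumor_fraction = 0.5,
                           seed = 1L) {
  stopifnot(n >= 1, tumor_fraction >= 0, tumor_fraction <= 1)
  n_pos <- round(n * tumor_fraction)
  pos <- with_seed(seed, sample.int(n, n_pos))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- as.integer((seed + 104729 * i) %% 2147483647)
    jit <- with_seed(si, list(
      center = round(runif(2, -6, 6)),
      axes = runif(2, 0.92, 1.08),
      t_angle = runif(1, 0, 2 * pi),
      t_rho = runif(1, 0.15, 0.55),
      t_rel_radius = runif(1, 0.15, 0.28)  # fraction of the minor semi-axis
    ))
    axes <- base$brain_axes * jit$axes
    center <- base$brain_center + jit$center
    t_center <- center + jit$t_rho * axes *
      c(cos(jit$t_angle), sin(jit$t_angle))
    spec <- base
    spec$brain_axes <- axes
    spec$brain_center <- center
    spec$tumor_present <- i %in% pos
    spec$tumor_center <- t_center
    spec$tumor_radius <- jit$t_rel_radius * min(axes)
    spec$seed <- si
    samples[[i]] <- generate_phantom(spec)
  }
  names(samples) <- sprintf("phantom_%03d", seq_len(n))
  samples
}

#' Write a phantom batch to disk
#'
#' Writes per-sample image and truth-mask PNGs, a `labels.csv`, and a VIA
#' JSON (`annotations.json`) in which each tumor disc is approximated by a
#' 36-gon, so the on-disk layout exercises the same readers as real data.
#'
#' @param samples Output of [generate_batch()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_batch <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(image_id = names(samples),
                       label = vapply(samples, function(s) s$label, 1L))
  via <- list()
  for (id in names(samples)) {
    s <- samples[[id]]
    png::writePNG(as_pixel_matrix(s$image), file.path(dir, paste0(id, ".png")))
    write_mask_png(s$brain_truth, file.path(dir, paste0(id, "_brain.png")))
    write_mask_png(s$tumor_truth, file.path(dir, paste0(id, "_tumor.png")))
    regions <- list()
    if (s$label == 1L) {
      th <- seq(0, 2 * pi, length.out = 37)[-37]
      regions <- list(list(shape_attributes = list(
        name = "polygon",
        all_points_x = s$spec$tumor_center[2] + s$spec$tumor_radius * cos(th),
        all_points_y = s$spec$tumor_center[1] + s$spec$tumor_radius * sin(th)
      ), region_attributes = list()))
    }
    via[[paste0(id, ".png")]] <- list(filename = paste0(id, ".png"),
                                      regions = regions)
  }
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(via, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
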