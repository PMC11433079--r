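---
title: "Refining perturbation-based explanations with a brain mask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining perturbation-based explanations with a brain mask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainlime)
```

## The problem

A perturbation-based local explainer attributes a classifier's decision to
superpixels of the input image: segments are randomly occluded, the model
is re-queried, and a sparse linear surrogate fitted to the responses
yields one importance weight per segment. On brain MRI slices this
routinely produces a characteristic artifact: segments **outside the
brain** — background, skull, scanner clutter — receive high importance,
because occluding them does move the model's score even though they carry
no diagnostic meaning. `brainlime` implements a post-hoc rule that removes
such segments using a brain mask derived from the image itself, and the
coverage metrics needed to quantify whether the rule helps.

## The surrogate model

For an image with $d$ segments, presence patterns $z \in \{0,1\}^d$ are
drawn i.i.d. Bernoulli(1/2) per segment (the first pattern is always the
all-ones original); 1000 perturbed images are used by default. Dropped
segments are filled either with the segment's own mean intensity
(`segment_mean`, the default) or with zeros. The surrogate is a weighted
ridge regression of the tumor-class probability on $z$,

$$\hat\beta = \arg\min_\beta \sum_k w_k\,(f(z_k) - \beta_0 - \beta^\top z_k)^2 + \lambda \lVert\beta\rVert^2, \qquad w_k = \exp\!\big(-d_{\cos}(z_k, \mathbf 1)^2 / \nu^2\big),$$

with kernel width $\nu = 0.25$ and penalty $\lambda = 1$ by default
(intercept unpenalized, not reported). Tunable parameters and their
rationale:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 1000 | perturbations per explanation; variance of the weights shrinks as $1/\sqrt{n}$ |
| `kernel_width` | 0.25 | locality of the fit around the unperturbed image (cosine distance) |
| `ridge` | 1 | stabilizes the fit when $d$ approaches `n_samples` |
| `fill` | `segment_mean` | occlusion value; `zero` for models that respond to raw brightness |
| `threshold` | 0.8 | refinement overlap fraction |

Two details are deliberate design choices rather than consequences of the
method. First, presence sampling is i.i.d. uniform over $\{0,1\}^d$; an
alternative scheme (draw a count $m < d$, then choose $m$ segments) gives
each pattern weight a different marginal and was not adopted — uniform
sampling keeps every column of the design balanced and the surrogate
unbiased for additive models. Second, `top_n_segments()` ranks by *signed*
weight and keeps only strictly positive ones, with ties broken by
ascending segment id for determinism: a segment whose removal *raises*
the tumor probability is evidence against the class, not an explanation
for it.

## Segmentation

Three grayscale oversegmenters are provided, with defaults chosen to give
a few dozen to ~100 segments on a 224×224 image: SLIC (`n_segments` 50,
`compactness` 10; local k-means in joint intensity/position space on a
0–100 intensity scale), quickshift (`kernel_size` 4, `max_dist` 200,
`ratio` 0.2; mode seeking on a kernel density, with a tiny seeded jitter
on the density so flat regions break ties reproducibly), and Felzenszwalb
(`scale` 100 on a 0–255 intensity scale, `sigma` 0.8, `min_size` 50;
graph-based merging). Labels are always relabeled to $0..d-1$ and the
partition property (every pixel in exactly one segment) is enforced and
tested. On constant images SLIC degenerates to near-equal rectangles —
a useful fixture for exact tests.

## Brain-mask extraction

All five detectors share the tail of the pipeline: binary response →
morphological closing (3×3 box, 2 iterations — closes gaps up to ~4 px
in thin contours) → 8-connected component labelling → per-component hole
filling → the component with the **largest enclosed area** becomes the
mask. Numerical choices worth recording:

* **Laplacian / Sobel binarization.** The raw responses are thresholded
  with Otsu on the absolute response, a parameter-free rule that treats
  all detectors uniformly.
* **Otsu.** Exhaustive search over 256 uniform bins on $[0,1]$ maximizing
  $V(t) = p_B p_F (\mu_B - \mu_F)^2$; class proportions and means are
  computed exactly from the pixel values (per-bin sums), not from
  bin-center approximations, and ties go to the lowest threshold.
* **Li.** Exhaustive 256-bin minimization of the cross-entropy objective
  $H_F(t) + H_B(t)$ with class means floored at $10^{-12}$ so exact-zero
  backgrounds stay comparable. The classic fixed-point iteration
  $t \leftarrow (\mu_F - \mu_B)/(\ln\mu_F - \ln\mu_B)$ stalls in shallow
  local minima on near-flat histograms, so the search is exhaustive; on
  well-separated bimodal data both routes coincide.
* **Canny.** Gaussian smoothing (σ = 2), Sobel gradients, non-maximum
  suppression over four quantized directions, hysteresis with *absolute*
  magnitude thresholds 0.1/0.2. Absolute thresholds keep the operator
  monotone in σ (more smoothing can only weaken gradients and prune
  edges); thresholds relative to the per-image maximum do not.
* **Connectivity.** Thin diagonal contours are 8-connected; component
  labelling therefore merges 4-connected labels that touch diagonally,
  and each component is hole-filled *in isolation* so that structure
  enclosed by a contour (e.g. the tumor's own edge ring) counts as
  inside it.
* **Fallback.** If no contour emerges or the winning mask covers less
  than 5% of the frame, the mask falls back to all-ones (configurable to
  all-zero) and is flagged. The all-ones fallback makes refinement the
  identity, so a mask failure can never delete a legitimate explanation —
  the failure mode observed with fragmented contours on real data.

## Refinement and metrics

The rule is exactly the inclusive comparison
$|S_i \cap \mathrm{BrM}| \ge \theta \cdot |S_i|$ with $\theta = 0.8$;
a segment with exactly 80% of its pixels inside the mask is retained. The
comparison carries a $10^{-9}$ slack because $0.8 \times 10 > 8$ in
binary floating point. Retained segments keep their original weights —
no renormalization — and dropped ones are zeroed, so refinement never
raises a weight and retained sets nest monotonically as $\theta$ grows
(both are tested properties). The default 0.8 sits between two failure
modes explored over 0.5–0.9: low thresholds keep out-of-brain clutter,
high thresholds discard boundary segments that only marginally leave the
brain.

TSC and BSC divide by the tumor and brain mask sizes respectively; both
error on an empty denominator rather than guessing. Top-$n$ selection is
applied **after** refinement for the refined arm and on the same heatmap
for the baseline arm, so the comparison isolates the effect of the rule
itself.

## What the phantoms emulate — and what they do not

`generate_phantom()` renders a 224×224 slice: an elliptical brain at
intensity 0.45 with Gaussian texture (σ = 0.03 inside, half that in the
background), a ~2.5 px skull-like rim at 0.9 hugging the ellipse, two
bright background artifact discs (radius 9, intensity 0.9) placed in the
corners, and optionally a tumor disc (intensity 0.85) strictly inside the
brain. Noiseless specs are exactly piecewise-constant, so thresholding
recovers the brain truth exactly — the anchor for mask-quality tests.
Batches jitter geometry deterministically per sample; tumor radii span
0.15–0.28 of the minor semi-axis so that superpixels sometimes split a
tumor, which is precisely the regime where a distractor can displace a
tumor segment from the top-3.

The artifact discs are sized comparably to tumors on purpose: they are
the out-of-brain structures that attract importance and give refinement
something to remove. The rim, by contrast, ends up *inside* every
detector's mask (the largest contour encloses it), so refinement
correctly leaves rim segments alone.

The mock predictors are deliberately simple. `intensity_predictor()`
scores the mean brightness of a fixed region through a logistic with
moderate slope (sharpness 8 in the harness — steep slopes saturate the
responses and flatten the surrogate's signal); `bright_region_predictor()`
points that region at the bright pixels of the reference image, emulating
a CNN that learned a brightness shortcut. Because this model responds
only to mean intensity, mean-fill occlusion is a no-op against it by
construction; phantom runs therefore use `fill = "zero"`.
`oracle_linear_predictor()` is exactly linear in segment presence and
serves as the parameter-recovery oracle for the surrogate.

What passing tests on phantoms do **not** show: anything about real MRI
texture, partial-volume effects, multi-slice anatomy, or a real CNN's
decision surface. The phantoms validate the *mechanics* — segmentation,
surrogate fidelity, mask extraction, the refinement rule, the metrics —
not the clinical claim that refined explanations of a particular trained
model are trustworthy.

## Problem sizes

The test-suite and acceptance runs use sizes chosen to exercise every
code path at full fidelity while staying desk-scale: 20-phantom batches
at 224×224 for the end-to-end grid, 1000 perturbations per explanation,
100 seeded runs for planted-signal recovery at 64×64 with ~10 segments,
50 noisy phantoms for median mask Dice, 200 random images for the
threshold oracles, 1000 random mask pairs for the coverage oracles, and
1000 simulations for the null calibration of the Kruskal–Wallis harness.

## Known limitations

* Quickshift's parent search is windowed at twice the kernel size, so
  `max_dist` only matters below that radius; the i.i.d. perturbation
  design and signed-positive ranking are documented choices, not the only
  defensible ones.
* The brain mask is the *largest* filled contour; images whose brain is
  split across disconnected regions (rare in axial slices) would lose the
  smaller part.
* BSC is computed against the detector-derived mask (optionally against
  phantom truth), so a poor mask biases BSC and the refinement equally —
  deltas remain interpretable, absolute BSC values less so.
* Explanations target the tumor-positive class only; class-0 explanations
  exist for testing (`require_positive = FALSE`) but are not part of the
  evaluation design.
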