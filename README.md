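# brainlime

Perturbation-based local explanations (LIME-style heatmaps) of brain-tumor
classifiers routinely assign importance to image regions that lie outside
the brain — background clutter, skull artifacts, scanner noise. For a
clinician, an "explanation" pointing at empty background is worse than no
explanation at all. `brainlime` implements a post-hoc refinement of such
heatmaps together with the metrics needed to audit them, aimed at anyone
evaluating saliency explanations of binary classifiers on grayscale 2D
medical images.

## Method

Given a grayscale image *I* classified tumor-positive by a model
*f(I) ∈ {0, 1}*:

1. **Explain.** Segment *I* into *d* superpixels (SLIC, quickshift, or
   Felzenszwalb). Draw presence patterns *z ∈ {0,1}^d*, occlude the absent
   segments, query the model, and fit a weighted ridge surrogate
   *f(z) ≈ β₀ + Σᵢ βᵢ zᵢ* with locality weights
   *exp(−d_cos(z, 𝟙)² / ν²)*. The heatmap is
   *H = {Sᵢ : βᵢ}*.
2. **Mask.** Extract a binary brain mask BrM: run one of five operators —
   Laplacian (∇²I with the 3×3 mask), Sobel gradient magnitude
   √(Gx² + Gy²), Canny edges, or Otsu / Li thresholding — then
   morphologically close the binary response, and fill the contour with
   the largest enclosed area.
3. **Refine.** Keep segment *Sᵢ* iff
   `|Sᵢ ∩ BrM| ≥ 0.8 · |Sᵢ|` (inclusive, threshold configurable over
   0.5–0.9); zero the importance of all others.
4. **Score.** For the union *E* of the top-*n* positive-importance
   segments:
   - **TSC** (Tumor Segment Coverage) = `100 · |E ∩ tumor| / |tumor|` —
     how much of the annotated tumor the explanation shows (higher is
     better);
   - **BSC** (Brain Segment Coverage) = `100 · |E ∩ BrM| / |BrM|` — how
     much healthy-looking brain it spends doing so (lower is better at
     fixed TSC).

A synthetic phantom generator (elliptical brain, bright skull rim, bright
background artifacts, optional tumor disc, ground-truth masks) and mock
predictors make the whole pipeline testable without MRI data or a trained
CNN; an evaluation harness runs the full segmenter × detector × top-n
grid with before/after deltas and rank-based statistics (Mann–Whitney,
Kruskal–Wallis).

## Worked example

```r
library(brainlime)

s <- generate_phantom(phantom_spec(seed = 9, tumor_radius = 18))
model <- bright_region_predictor(s$image)   # brightness-shortcut mock CNN

hm <- explain_image(s$image, model, algorithm = "quickshift",
                    seed = 9, fill = "zero")
segmap <- attr(hm, "segmap")
report <- build_brain_mask(s$image, detector = "otsu")
refined <- refine(hm, segmap, report$mask, threshold = 0.8)

before <- coverage_result(hm,      segmap, n = 3, tumor = s$tumor_truth,
                          brain = report$mask)
after  <- coverage_result(refined, segmap, n = 3, tumor = s$tumor_truth,
                          brain = report$mask)
sprintf("top-3 TSC: %.2f%% -> %.2f%%   BSC: %.2f%% -> %.2f%%",
        before$tsc, after$tsc, before$bsc, after$bsc)
```

prints

```
<phantom_sample 224x224, label=1, brain=17329 px, tumor=1012 px>
<lime_heatmap: 114 segments, class 1; top: 69=0.365, 17=0.121, 102=0.12, ...>
<mask_report otsu: 3 contour(s), 37.3% of frame>
<refined_heatmap: 38 retained / 76 dropped at threshold 0.80>
top-3 TSC: 74.80% -> 100.00%   BSC: 4.04% -> 9.45%
```

Two of the three strongest segments (ids 17 and 102) were bright
background artifacts; refinement zeroes them, the next tumor-overlapping
segments move into the top 3, and tumor coverage rises from 74.8% to
100% while the explanation still touches under 10% of the brain mask.

Batch experiments follow the same shape:

```r
samples <- generate_batch(20, phantom_spec(), tumor_fraction = 1, seed = 1)
records <- run_grid(samples, model = function(s) bright_region_predictor(s$image),
                    segmenters = c("quickshift", "slic"),
                    detectors = c("canny", "laplace", "li", "otsu", "sobel"),
                    ns = c(1, 3, 5), seed = 1, fill = "zero")
summarize_records(records)   # group means, deltas, |delta| > 1 subset
write_report(records, "report/")
```

A thin command-line dispatcher covering the phantom / brainmask / refine /
evaluate stages ships in `inst/cli/brainlime.R`.

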