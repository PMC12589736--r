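---
title: "histofuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histofuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(histofuse)
```

histofuse implements a complete diagnosis pipeline for multiclass
histopathology tiles — the five lung/colon lesion classes of LC25000-style
datasets are the motivating case — in which classical image processing and
tree ensembles are fused with deep-feature representations:

1. **Enhancement** by filter fusion: a 5×5 mean filter suppresses staining
   artifacts, a Laplacian re-emphasizes edges, and the sharpened image is
   their difference.
2. **Segmentation** of the diseased-tissue region with a region-based
   geometric active contour (the Chan–Vese energy), exporting a
   region-of-interest (ROI) image per tile.
3. **Feature extraction**: each ROI passes through one or more feature
   extractors behind a pluggable contract, and each spatial feature map is
   collapsed by global average pooling (GAP) into a per-image vector.
4. **Serial fusion**: vectors from several extractors are concatenated
   end-to-end into one wide feature matrix.
5. **Selection**: ant-colony optimization (ACO) retains a compact
   discriminative subset of the fused features.
6. **Classification** with a decision tree (DT) and a random forest (RF),
   evaluated with one-vs-rest per-class metrics, macro averages, and paired
   t-tests between strategies.

This vignette records the model choices, the tunable parameters, and the
reasoning behind every decision the design left open.

## Enhancement

The mean filter replaces every pixel by the average of its 5×5
neighborhood (25 samples); the Laplacian is the fixed second-difference
stencil

```
0  1  0
1 -4  1
0  1  0
```

and the enhanced image is `mean_filter(I) - laplacian_filter(I)`, clipped
to [0, 1]. Three choices deserve a note:

* **Stencil sign convention.** A "positive center" Laplacian is the
  negation of this stencil; we treat the printed stencil itself as
  normative. Consequently the response to `f(i,j) = i^2` at interior
  pixels is `+2` (the second difference `(i-1)^2 - 2i^2 + (i+1)^2 = 2`),
  and subtracting the Laplacian in the fusion step brightens pixels that
  are locally darker than their surroundings — the usual sharpening
  behavior.
* **Borders** use symmetric reflection. Zero padding would create dark
  halos at tile borders on bright histology backgrounds, which the
  downstream contour would latch onto.
* **Clipping, not renormalizing.** The subtraction can leave [0, 1];
  renormalizing would rescale contrast globally and undo the local
  sharpening, so values are clipped instead.

RGB input is filtered per channel. Segmentation, however, always runs on
the grayscale (BT.601) image: the contour model below is a scalar-intensity
model, and the data gave no reason to prefer a per-channel variant.

## Geometric active contour

The contour `C` is the zero level of a scalar field `phi` (inside:
`phi > 0`) and minimizes

    G(C) = sum_outside (I - m1)^2 + sum_inside (I - m2)^2 + beta * length(C)

with `m1`, `m2` the mean intensities outside/inside and `beta >= 0` the
length penalty. Gradient descent updates `phi` in the smoothed band around
the contour by the force `(I - m1)^2 - (I - m2)^2 + beta * kappa`, where
`kappa` is the curvature of the level sets; a smoothed delta
(`eps = 1` pixel) confines the update to the contour band, and the same
smoothing defines the co-area contour-length estimate.

Numerical choices, all visible in `gac_config()`:

* **Force normalization and `dt = 1`.** The data force is divided by its
  maximum magnitude, so `dt` is the contour speed in pixels per iteration
  regardless of image contrast. `phi` is re-initialized to a signed
  distance every 20 iterations to prevent flattening; a re-initialization
  resets boundary `|phi|` to about 1, so the per-iteration update
  (`<= dt * 0.32`) must be able to cross that gap within one cycle —
  `dt = 1` does, while `dt = 0.5` deadlocks the contour against the
  re-initialization. This is why the default is 1.
* **Energy bookkeeping.** Evolution distorts `|grad phi|`, which corrupts
  the smoothed length estimate if evaluated on the raw field. The recorded
  trace therefore evaluates the energy on a signed-distance normalization
  of `phi`: the trace is a function of the contour alone, changes only when
  pixels change side, and is non-increasing on the benchmark problems.
* **Convergence** is declared when the relative energy change stays below
  `tol = 1e-4` for a full re-initialization cycle (20 iterations); a single
  quiet step is not convergence, because the trace only moves when contour
  pixels flip.
* **Polarity.** The energy is symmetric in the two regions, so "which side
  is the lesion" is undecidable from the model. The region whose mean lies
  farther from the image median is labelled foreground; this recovers
  lesions in both bright-on-dark and dark-on-bright contrast.
* **Degenerate input.** A constant (or contrast-free) image makes
  `m1 = m2`; segmentation raises an error rather than returning an
  arbitrary full or empty mask.
* An optional edge-stopping weight `1/(1 + |grad I|^2)` can multiply the
  force (`edge_weight = TRUE`); it is off by default because the energy
  contains no edge term. The descent steps the model describes as "image
  gradient forces" are realized by the data term pulling the contour to
  intensity boundaries.

Masks are post-processed by removing components below 1% of the tile area,
filling holes, and optionally dropping components under half the largest
one. The ROI export masks the *original* RGB tile (not the enhanced one),
so feature extraction sees unaltered tissue intensities.

## Feature extraction and fusion

`max_pool()`/`avg_pool()` implement the square-window pooling forms with
stride `p` (output `floor((H-k)/p)+1` per side), and `global_avg_pool()`
averages each channel over all positions. Extractors are pluggable
(`extractor_spec()`): production use can wire real pretrained ResNet50 /
DenseNet169 / MobileNet backbones behind the contract; the package builds
and tests with deterministic stand-ins (`standin_extractor()`) that
summarize each tile on a 4×4 lattice of patch statistics (local mean,
spread, Laplacian energy, gradient energy, channel means, dark/bright
fractions) passed through a fixed seeded random projection. The stand-in
presets declare the documented widths 1024 (resnet50), 1664 (densenet169)
and 2048 (mobilenet), so the fused triple matrix is 4,736 wide; these
widths are kept as documentation-traceable defaults, and any extractor's
actual reported width always wins.

Fusion is plain end-to-end concatenation in the given order; sample ids
and labels must align exactly. No column normalization is applied before
classification: the stand-in features are already bounded, tree-based
classifiers are scale-invariant, and no procedure was specified to the
contrary.

## Ant-colony feature selection

No closed-form construction rule is canonical for feature-subset ACO, so
the classic ant-system rule is used: each of `n_ants` ants draws
`subset_size` distinct features sequentially with probability proportional
to `tau^alpha * eta^gamma`, where `tau` is the pheromone trail and `eta` a
fixed heuristic importance (the one-way ANOVA F statistic of feature
against class). After each iteration all trails evaporate by `1 - rho` and
the iteration-best subset deposits `Q * score`; trails are floored at
1e-12. The objective is the mean stratified 3-fold CV accuracy of a
shallow decision tree (depth ≤ 8) on the candidate columns, evaluated with
one fixed fold seed per run so the objective is a pure function of the
subset. The run stops at `max_iters` or when `1 - best_score` reaches
`error_threshold`.

Defaults: `n_ants = 20`, `rho = 0.1`, `tau0 = 0.1`, `alpha = gamma = 1`,
`Q = 1`, `max_iters = 100`, `error_threshold = 0.01`. A greedy mode
(`greedy = TRUE`) takes the top-weight features deterministically, the
limit behavior of `alpha -> Inf`. Deposit uses the iteration best only, to
sharpen convergence toward "the best subset".

The retained-subset sizes follow the documented per-combination defaults —
resnet50+densenet169 → 625, densenet169+mobilenet → 690,
resnet50+mobilenet → 720, all three → 810 — mapped in that printed order
(the source never states the mapping explicitly); any `subset_size`
overrides them.

## Partitioning, augmentation, classifiers

`stratified_split()` allocates per class: 60% to a pool, 90% of the pool
to training and 10% to validation, the remaining 40% to test, flooring at
each stage with remainders falling to the last partition. 5,000 per class
gives exactly 2,700 / 300 / 2,000.

`augment_training()` expands each training record into itself plus five
transformed copies (rotation ±15°, shifts ±10%, shear ±10%, zoom ±5%,
coin-flip horizontal flip), drawn from a seeded stream — 2,700 training
tiles become 16,200 records per class. The plan is lazy: records carry
their transform parameters, and `apply_augmentation()` materializes warped
pixels (bilinear sampling, reflected boundaries — the same border policy
as the filters) only when needed. Augmentation applies to training records
only, and the default feature pipeline runs on original tiles (the fused
matrices are defined per original image); image-level augmentation remains
available for training image-domain models.

The DT is a CART tree (Gini, grown to purity — no depth cap); the RF
aggregates 200 bootstrap trees with `sqrt(D)` feature subsampling and
majority voting, both seeded. Class scores are leaf frequencies (DT) and
tree-vote fractions (RF).

One ordering decision: the pipeline splits *before* ACO selection and runs
the selection objective on the training pool only, so the held-out test
set never influences which features are kept. (The protocol description
orders selection before splitting; running selection on all rows would
leak test labels into the objective, so the package orders the stages
defensively. The reported arithmetic is unaffected.)

## Evaluation

Per class (one-vs-rest): sensitivity `TP/(TP+FN)`, accuracy
`(TP+TN)/total`, precision `TP/(TP+FP)`, specificity `TN/(TN+FP)` — all
percentages — and F1 as the harmonic mean of precision and sensitivity.
Macro rows are unweighted means; overall top-1 accuracy is reported
alongside. A zero denominator yields an explicit `NA`, never a silent 0.

AUC deserves a note: the source ratio form "TP rate / FP rate" is
unbounded and cannot produce the percentage-scale values reported
alongside it, so the standard definition is implemented — the
tie-corrected rank (Mann–Whitney) statistic, identical to the trapezoidal
area under the ROC curve — one-vs-rest per class, macro-averaged.

`paired_f1_ttest()` compares two models over their per-class F1 vectors as
paired observations (5 classes → df = 4): `Delta = mean(a-b)`,
`t = Delta / (sd(a-b)/sqrt(n))`, with a **one-sided** p-value for the
alternative that the first model scores higher (that is the stated
hypothesis when comparing fused against single-backbone models) at
`alpha = 0.05`. Zero-variance differences are flagged explicitly: `t` is
unbounded when `Delta != 0`, and a no-difference result otherwise.

## Synthetic data: what it emulates, and what it does not

`generate_tile()` draws one lobed foreground region (a radially perturbed
disk at a 25–55% area fraction) over a darker background, fills it with
Poisson-placed dark "nuclei" disks, adds Gaussian texture noise
(sd 0.05), and tints the result H&E-like (nuclei darker and bluer than
stroma, matching real hematoxylin contrast). Class identity is carried by
nucleus density alone. The default density ladder doubles per class
(8, 16, 32, 64, 128 nuclei per 1,000 foreground pixels) with radii 1–2 px:
with doubling, adjacent classes differ in expected nucleus count by well
over the Poisson spread even on small tiles, which is what makes the
classes genuinely separable at desk scale — a generator whose classes
overlap by construction would test nothing but noise.

What the generator does **not** emulate: stain variability, glandular and
nuclear morphology, texture anisotropy, out-of-focus blur, and the
correlated background structure of real tissue. A pipeline that passes the
synthetic benchmarks is verified as *mechanically correct and
discriminative when a signal exists*; no claim about real-tile accuracy
follows.

Problem sizes used by the test-bench configurations are package choices:
64×64 tiles for the segmentation benchmarks and the end-to-end run, 5
classes × 40 tiles end-to-end (120 non-test rows for selection, 80 test
rows), and a 5-iteration ACO budget in the desk configuration (the
error-threshold stop usually fires earlier on separable data). The
per-class partition at 40 tiles is 21 train / 3 validation / 16 test.

## Known limitations

* The contour model is two-phase: one lesion region per tile. Multi-focal
  lesions survive only via the connected-component post-processing.
* The ACO objective refits a tree per ant and iteration; for very wide
  matrices the selection stage dominates runtime. The iteration cap and
  error threshold are the intended controls.
* The paired t-test on 5 class-wise F1 values has low power and assumes
  approximate normality of the differences; it mirrors the published
  protocol rather than a recommendation.
* Stand-in extractors share the *interface* of pretrained backbones, not
  their representational power.
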