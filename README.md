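# histofuse

Multiclass histopathology tile diagnosis by fusing classical image
processing with deep-feature representations and tree ensembles. The
package is aimed at computational-pathology practitioners who want a
fully inspectable, dependency-light implementation of this pipeline —
every stage runs and is tested on seeded synthetic tiles, with no
dataset download or pretrained weights required.

The pipeline, end to end:

1. **Enhancement** — filter fusion: `mean5x5(I) − ∇²I`, clipped to
   [0, 1]. The 5×5 mean suppresses staining artifacts; subtracting the
   Laplacian (stencil `[0,1,0; 1,−4,1; 0,1,0]`) restores edge contrast.
2. **Segmentation** — a region-based geometric active contour. The
   contour *C* is the zero level of a field φ minimizing the Chan–Vese
   energy

   ```
   G(C) = Σ_outside (I − m₁)² + Σ_inside (I − m₂)² + β·length(C)
   ```

   with m₁/m₂ the outside/inside mean intensities and β a length
   penalty. The diseased-tissue mask is exported as a region of
   interest (ROI) over the original RGB tile.
3. **Feature extraction** — any extractor implementing the
   `extractor_spec()` contract (image → H×W×C feature map); maps are
   collapsed by global average pooling into per-image vectors.
   Deterministic stand-in extractors with the documented widths
   1024 / 1664 / 2048 ship with the package.
4. **Serial fusion** — end-to-end concatenation of per-image vectors
   across extractors (triple fusion: 4,736 features).
5. **Selection** — ant-colony optimization: ants build feature subsets
   with probability ∝ τᵅ·ηᵞ (pheromone × ANOVA-F importance), scored by
   cross-validated decision-tree accuracy, with evaporation and
   iteration-best deposit.
6. **Classification & evaluation** — CART decision tree and a
   200-tree random forest; one-vs-rest sensitivity / accuracy /
   precision / specificity / F1 / AUC per class with macro averages,
   and paired per-class-F1 t-tests between strategies.

## Worked example

Segment a synthetic tile and select features on a planted problem:

```r
library(histofuse)

d   <- generate_tile(tile_spec(size = c(64, 64)), class_index = 4, seed = 42)
enh <- enhance(to_grayscale(d$image))
seg <- gac_segment(enh, gac_config())
seg
#> <segmentation_result> 64 x 64, foreground 47.0%, m1 = 0.269, m2 = 0.475,
#>   energy 378.4 after 207 iterations (converged)
dice_coefficient(postprocess_mask(seg$mask), d$mask)
#> [1] 0.948
```

The contour found the lesion (mean intensity 0.475 inside vs 0.269
outside) and overlaps the generator's truth mask at Dice 0.95.

```r
prob <- generate_feature_problem(n = 100, d = 20, k = 4, effect_size = 2, seed = 1)
res  <- run_aco(feature_values(prob$features), prob$features$label,
                aco_config(subset_size = 4, n_ants = 10, max_iters = 15, seed = 1))
res
#> <selection_result> 4 features selected, best score 0.9190 after 15 iterations
prob$informative   # planted: 6 13 14 18
res$best_subset    # selected: 6 9 13 14
```

Three of the four planted informative columns are recovered; the best
subset reaches 91.9% cross-validated accuracy. `tidy()` / `glance()`
return the score trace and summary; `autoplot()` draws the trace, the
segmentation overlay, or a metrics panel.

The whole chain runs from one config:

```r
cfg <- pipeline_config(
  out_dir   = "run1", seed = 11,
  synthetic = list(spec = tile_spec(size = c(64, 64)), n_per_class = 40L),
  aco       = aco_config(max_iters = 5L)
)
manifest <- run_pipeline(cfg)   # enhance → segment → extract → fuse →
                                # select → split → train → evaluate → compare
```

which writes every intermediate artifact (feature CSVs, selection JSON,
split, per-model reports, DT-vs-RF comparison) plus a hashed manifest
under `out_dir`, and is resumable per stage. A thin command-line front
end is installed at `inst/scripts/histofuse.R`
(`histofuse.R synth|run|compare`).

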