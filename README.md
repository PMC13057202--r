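# mangroveCarbon

Species-level carbon stock assessment for mangrove stands from five-band
multispectral rasters (B, G, R, red-edge, NIR) and a photogrammetric surface
model. The package is aimed at coastal remote-sensing and blue-carbon
researchers who need a reproducible, testable version of the common UAV
workflow: map *which* species grows where, then apply *species-specific*
carbon models instead of a single stand-level regression.

Because mangrove species differ strongly in stature and carbon density,
ecosystem-level regressions blur exactly the signal that matters; the
pipeline here keeps species identity explicit end to end. Everything runs on
synthetic scenes with known ground truth, so every stage can be validated
against the generative parameters.

## What it computes

**Features.** From the bands: nine vegetation indices (NDVI, GNDVI, NDRE,
OSAVI, LCI, RVI, MACI, VREI, SR); from the surface model a canopy height
model CHM = DSM − DTM, with the DTM interpolated from ground control points
by inverse-distance weighting (ẑ(x) = Σ wᵢzᵢ/Σ wᵢ, wᵢ = dᵢ⁻ᵖ, parameters
picked by leave-one-out RMSE); and eight gray-level co-occurrence (GLCM)
texture metrics per band (Con, Cor, Dis, Ent, Hom, Mean, Asm, Var) over a
moving window — 55 co-registered layers in all.

**Classification.** Gaussian maximum likelihood: each class k is a fitted
multivariate normal and a pixel x gets the label maximizing

    g_k(x) = ln π_k − ½ ln|Σ_k| − ½ (x − μ_k)ᵀ Σ_k⁻¹ (x − μ_k)

Feature combinations V1–V15 (visible bands, band/index sets, each ± canopy
height, up to the full fusion V15) are compared on a stratified 70/30 split
with confusion-matrix metrics: overall accuracy (OA), producer's and user's
accuracy (PA/UA) per class.

**Carbon models.** Per-tree field measurements become plot AGC/BGC through a
registry of species-specific allometric power laws and carbon conversion
factors. Plot-level features are screened by Pearson correlation; univariate
and multivariate linear models are filtered by coefficient significance
(p < 0.05) and variance inflation (VIF < 3, gross collinearity flagged at
10), then ranked by leave-one-out cross-validation R². Species may share one
model: all 15 candidate groups (4 singletons + 11 multi-species pools) are
evaluated and the best partition of the species set is selected.

**Mapping.** The selected models are applied per classified pixel; total
carbon adds a per-species soil constant, TGC = AGC + BGC + soil(species).
Outputs: AGC/BGC/TGC rasters, transect profiles, per-species area and stock
summaries.

## Worked example

```r
library(mangroveCarbon)

smap  <- generate_species_map(200, 200, seed = 1,
           fractions = c(B_gymnorrhiza = 0.08, R_stylosa = 0.20,
                         A_marina = 0.24, A_corniculatum = 0.13,
                         soil = 0.15, water = 0.12, shadow = 0.08),
           patch_scale = 15)
scene <- generate_scene(smap, default_signatures(), seed = 2)
plots <- sample_plots(scene, n_per_species = 10, seed = 3)   # 40 field plots
stack <- feature_stack(scene, textures = TRUE, glcm_levels = 32)
tab   <- aggregate_to_plots(stack, plots)

ev <- evaluate_combinations(smap, stack,
        default_combinations()[c("V1", "V4", "V8", "V15")], seed = 4)
ev$ranking[, c("combination", "n_features", "oa")]
#>   combination n_features    oa
#> 1          V4          5 1.000
#> 2         V15         15 0.996
#> 3          V8          4 0.912
#> 4          V1          3 0.871
```

Adding red-edge/NIR (V4) or canopy height (V8) lifts OA over the visible
bands alone (V1) — heights separate the tall *R. stylosa* from the shorter
*A. marina* and *A. corniculatum* even where spectra are close.

```r
reg <- select_models(tab)
reg
#> == AGC (mean LOOCV R2 0.797) ==
#> AGC = 313.4 RE_Hom -182.1
#>   species : A_corniculatum + R_stylosa
#>   fit R2 0.860 | LOOCV R2 0.829 | LOOCV RMSE 11.87 t/hm2 | n 20
#> AGC = 855.9 NIR -377.5
#>   species : A_marina + B_gymnorrhiza
#>   fit R2 0.813 | LOOCV R2 0.766 | LOOCV RMSE 10.17 t/hm2 | n 20
#> ...

maps <- apply_models(smap, stack, reg)
species_summary(maps, smap)[, c("species", "area_hm2", "mean_agc", "pct_agc")]
#>          species area_hm2 mean_agc pct_agc
#> 1  B_gymnorrhiza  0.08989    67.02   14.88
#> 2      R_stylosa  0.22472    91.32   50.68
#> 3       A_marina  0.26966    32.69   21.77
#> 4 A_corniculatum  0.14607    35.12   12.67
```

Mean mapped AGC per species (t/hm²) recovers the generative community
levels: tall *R. stylosa* stands carry roughly three times the per-area
carbon of the shrubby *A. marina*.

The same workflow runs as five shell stages via
`inst/scripts/mangrove_pipeline.R` (`simulate`, `features`, `classify`,
`model`, `map`), each reading/writing plain-text artifacts plus a hashed
run manifest.

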