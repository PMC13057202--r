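---
title: "Species-level mangrove carbon estimation: methods and design notes"
output: rmarkdown::html_document
---

This vignette documents the science and the design decisions behind
`mangroveCarbon`: what each stage assumes, which parameters matter, what the
synthetic scenes do and do not emulate, and where the design was genuinely
open.

## The estimation problem

Mangrove species differ strongly in stature, density and carbon density, so
a single stand-level regression from imagery to carbon conflates species
composition with condition. The workflow implemented here keeps species
identity explicit: classify each pixel to species from spectral, structural
and textural features, then apply the carbon model *routed* to that species
(possibly shared by a group of species), and only then aggregate. Ground
truth enters twice — labeled pixels for classifier training/validation, and
a small set of field plots (here 5 m × 5 m, ten per species) whose per-tree
measurements are converted to plot carbon through allometric equations.

## Feature extraction

**Spectral.** Nine vegetation indices with the standard literature
definitions (documented in `?compute_index`); each formula is replaceable
via the `formulas` argument because acquisition software differs in its
exact definitions of LCI, SR, RVI and the red-edge ratios. `SR` is assigned
NIR/B to keep it distinct from `RVI` = NIR/R; both are configuration, not
commitments. Division-by-zero pixels become nodata rather than infinities.

**Structural.** The canopy height model is DSM − DTM. The DTM comes from
inverse-distance weighting over surveyed ground control points;
`select_idw_params()` picks `(pixel_size, power, n_points)` by
leave-one-GCP-out RMSE. Because a pure point prediction cannot depend on
pixel size, the held-out GCP is predicted at the centre of the grid cell
that would contain it — the way a gridded terrain product is actually
validated. Negative CHM values (terrain interpolation overshooting the
canopy) are physically impossible and are clamped to zero with a count kept
in the `"clamp_count"` attribute, so silent clamping is visible.

**Textural.** Eight gray-level co-occurrence metrics per band. The
conventional defaults — 3×3 window, four offsets {(0,1), (1,1), (1,0),
(1,−1)} pooled, symmetric counting — are exposed as parameters because the
tool chains that popularized GLCM texture differ in all three. Quantization
is global min–max over the raster, not per window: per-window quantization
would make the texture scale drift with local contrast and decouple the
metric from the scene-wide gray-level geometry. The `Mean`/`Var` metrics
are marginal statistics of the (symmetric) co-occurrence distribution, and
correlation is defined as 0 where a marginal standard deviation vanishes
(constant window). Windows are truncated at image edges rather than padded,
so border pixels use genuine data only.

## Classification

`mlc()` fits one multivariate Gaussian per class (sample mean, n−1
covariance) and classifies by the quadratic discriminant; priors default to
equal since a visual-interpretation training set does not estimate areal
prevalence. A ridge (default 1e-6) is always added to the covariance
diagonal and escalated tenfold until the Cholesky factorization succeeds;
escalation beyond a positive-definite raw covariance raises a warning so
degenerate feature sets (duplicated or clipped-constant layers) are
noticed, not masked. Ties break toward the lowest class index for
determinism. Accuracy is assessed on a stratified 70/30 split with OA and
per-class PA/UA; OA equals the reference-frequency-weighted mean of PA,
which the tests assert as an internal consistency check.

The V1–V15 combination definitions are configuration with defaults fixed by
the comparisons they support (visible bands vs + red-edge/NIR; each index
set vs the same set + canopy height; the full fusion V15). The membership
of the index-only sets V5–V7 and the band+index variants V13–V14 is an open
choice; the defaults are reasonable placeholders and `evaluate_combinations`
accepts any named list.

## Carbon models

Plot-level features are the means of the pixels whose centres fall in the
plot polygon (half-open edges, so adjacent plots never share pixels).
Screening and fitting follow the standard small-n workflow: Pearson
correlation ranking; univariate OLS on the top-|r| variable; exhaustive
multivariate search over subsets (size ≤ 3 by default) of the top-k
candidates, rejecting subsets with max VIF ≥ 3 (gross collinearity flagged
at 10) or any slope p ≥ 0.05; survivors ranked by leave-one-out R². With
n = 10 plots per species, exhaustive search over small subsets is exact and
reproducible where stepwise procedures are neither. No multiple-testing
correction is applied, matching the practice this implements.

LOOCV R² uses the PRESS form 1 − Σ(yᵢ − ŷ₍₋ᵢ₎)²/Σ(yᵢ − ȳ)² with the global
mean; it can legitimately be negative for uninformative models and the
tests assert that behaviour rather than clipping it.

Species pooling: all 15 candidate groups (4 singletons, 6 pairs, 4 triples,
1 quadruple) are fitted per response; the selected registry is the partition
of the species set maximizing mean LOOCV R² across blocks, ties broken by
fewer groups then lower summed RMSE. This formalizes as an explicit
objective what is otherwise a manual "compare R² and RMSE" judgement; the
full candidate table is always returned so the choice is auditable.

## Carbon mapping

Models are evaluated per classified pixel; negative predictions (inevitable
with strongly negative intercepts at low predictor values) are clamped to
zero and counted. Total carbon adds a per-species soil constant
(`soil_carbon_table()`, t/hm²) joined by the classified label — soil carbon
is treated as a species-level constant, not modeled. Non-vegetation classes
are nodata, so TGC is additive exactly where defined. Transects sample the
nearest pixel (no interpolation) to preserve the per-pixel model outputs.

## The synthetic scene generator

The generator defines the study conditions; it is parameterized by field
community statistics, not tuned to any test:

* Heights: *A. marina* 2.44 ± 0.50 m, *A. corniculatum* 1.83 ± 0.46 m,
  *R. stylosa* 4.73 ± 0.72 m, *B. gymnorrhiza* 2.51 ± 0.65 m.
* Densities: 9280, 133200, 7480 and 8320 trees/hm²; per-plot tree counts
  are Poisson(density × area) since only mean ± SD densities are reported
  in ground surveys.
* Reflectance: no absolute per-species reflectances are available, so the
  default signatures encode only the reported ordinal structure (all
  species brightest in G and darkest in B among the visible bands;
  *B. gymnorrhiza* highest in R/G, *R. stylosa* lowest, *A. marina* highest
  in B, *A. marina*/*A. corniculatum* similar and intermediate), with
  magnitudes chosen once so that the default per-band noise (sd 0.01)
  leaves every mangrove pair at Mahalanobis separation ≥ 5 — the regime in
  which a Gaussian classifier should recover the map almost perfectly, and
  the baseline the recovery tests assume. `band_sd` is the separability
  dial: larger values move OA continuously toward chance.
* Spatial structure: the species map thresholds one Gaussian-smoothed
  random field at the cumulative class fractions, giving contiguous patches
  whose realized areas are exact to pixel rounding. Class order in the
  fractions vector maps to bands of the field; the defaults place the
  smallest species class at a field tail, where patches are compact blobs
  rather than thin shells, keeping 5 m pure-plot placement feasible.
  Within-class reflectance and height noise are smoothed at the class
  `texture_scale` and re-standardized, so class means and marginal
  variances are preserved while GLCM contrast/homogeneity differ by
  species — texture is induced statistically, not by modeling canopies.
* Allometry: the shipped registry uses height-based power laws
  AGB = a·h² with carbon factor 0.46, with `a` calibrated per species and
  component so simulated plots reproduce the community AGC/BGC means (e.g.
  *R. stylosa* AGC ≈ 96 t/hm²) at the community densities; E[h²] = μ² + σ²
  enters the calibration. These are synthetic stand-ins with the same form
  as published species-specific equations; real analyses must supply their
  own registry JSON.

What the generator does **not** emulate: photogrammetric artifacts,
radiometric miscalibration, tidal inundation, canopy 3-D structure, mixed
pixels at crown boundaries, or spatial autocorrelation between plot carbon
and its neighbours. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated generative model, not field accuracy
of any particular coefficient set.

## Field plots

`sample_plots()` places non-overlapping 5 m squares inside ≥ 90%
single-species patches. Eligibility is computed exactly with an integral
image over pixel-centre labels, and placement is a deterministic greedy
row-major packing over eligible positions — randomized placement wastes
eligible positions on thin patches and fails unnecessarily. Randomness
(tree counts, heights, diameters) remains seed-driven. Plot carbon is
derived through the same registry the analysis uses, so the generative
AGC/BGC is known exactly and the allometric loop closes bit-for-bit.

## Numerical choices

* Rasters are row-major, origin top-left, pixel centres at half-integer
  offsets; coordinates in metres; nodata −9999 on disk (`.asc`), `NA` in
  memory.
* Block-mean aggregation (`resample_raster`) uses the nearest integer
  factor and records the achieved pixel size; a coarse cell is nodata when
  more than half its fine pixels are.
* IDW returns the stored elevation exactly when a query is within 1e-9 m of
  a GCP, avoiding 0⁻ᵖ.
* OLS is delegated to `lm`/`lm.fit`; the tests cross-check coefficients
  against the normal equations to 1e-8 and LOOCV folds against hand-fitted
  folds to 1e-10.
* All stage randomness derives from one root seed with fixed offsets, and
  reruns are manifest-hash identical.

## Problem sizes

The default study design — chosen as a realistic desk-scale stand — is a
200×200-pixel scene at 0.53 m (≈ 1.1 hm²), seven land-cover classes, ten
5 m plots per species, 60 GCPs, GLCM at 32 gray levels, and ≤ 2000 labeled
pixels per class for classifier scoring. The full five-stage pipeline on
this design completes in well under a minute on one CPU; the
coefficient-recovery experiments use 100 replicates of 10-plot fits.

## Known limitations

* The maximum-likelihood classifier is one-shot: no iterative training-set
  refinement, no object-based segmentation, no modern ML baselines.
* Linear carbon models only — with 10 plots per species anything richer
  overfits, but the restriction is structural.
* Soil carbon constants are applied per species with no spatial variation.
* The default signatures, combination memberships and allometric registry
  are synthetic scaffolding for validation; substantive use requires
  locally calibrated values for all three.
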