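# wmsubtypes

Multi-parametric quantitative MRI (qMRI) measures absolute tissue
parameters — longitudinal and transverse relaxation rates (R1, R2, the
effective rate R2\* and the field-inhomogeneity part R2′ = R2\* − R2),
diffusion-tensor scalars (axial/radial diffusivity AD/RD, mean diffusivity
ADC, fractional anisotropy FA), magnetic susceptibility (χm) and the
macromolecular proton fraction (MPF, a myelin proxy). Treating each map as
a different "staining" of the same tissue, spatially segregated white-matter
(WM) regions can be characterized by their *fingerprint*: the vector of
parameter values specific to that tissue class.

`wmsubtypes` implements the full analysis chain for data-driven WM
subtyping, for neuroimaging researchers working with co-registered
quantitative maps (or raw multi-contrast volumes):

1. **Parameter-map fitting** — R2\* by log-linear regression over a
   multi-echo gradient-echo stack; B1 from actual flip-angle imaging
   (AFI); B0 from a two-echo phase difference; R1 from two-point variable
   flip angle (VFA) SPGR with B1 correction and a pluggable spoiling
   correction; MPF by the single-point method, solving a constrained
   pulsed two-pool magnetization-transfer model (T2b = 9.7 µs,
   T2f = 0.022 T1, k(1−f)/f = 19 s⁻¹, R1f = R1b = R1) per voxel; R2 from
   partially spoiled SSFP (pSSFP) with an assumed global T1 = 1.25 s and a
   150 ms T2 cap; DTI eigen-metrics from a log-linear tensor fit.
2. **Group spatial ICA** — maps are smoothed (5 mm FWHM), intensity-
   normalized at the group level (one mean/SD per parameter over all
   subjects' in-brain voxels, clamped to ±4 SD), stacked into a
   (subject × parameter) × voxel matrix, and decomposed by
   information-maximization ICA at several model orders N. Components are
   kept as WM subtypes when their positive z ≥ 2 distribution overlaps WM
   and the ratio of between-parameter over between-subject loading SD
   exceeds 1.5.
3. **Reproducibility** — components are matched across model orders by
   optimal assignment on spatial correlation, agreement is quantified with
   Fleiss' κ on binarized maps (z ≥ 2 and z ≥ 3.2), and matched maps are
   averaged into a subtype atlas.
4. **Fingerprint statistics** — subtype fingerprints are extracted from the
   *unsmoothed* maps inside the atlas ROI (z ≥ 3.2, subject WM probability
   > 0.8) and compared by paired t-tests, Cohen's-d contribution ledgers
   (d = (m₁−m₂)/√((s₁²+s₂²)/2); Σ|d| estimates the inter-subtype distance),
   within-subtype cross-correlations, a repeated-measures GLM of subtype ×
   age/gender (Wilks' lambda omnibus plus univariate models), and
   tract-overlap proportions at z > 2.
5. **Synthetic phantom cohort** — a seeded generator mixing three latent
   spatial components with realistic WM fingerprints into per-subject maps
   (subject variability, planted age/gender effects, map noise, missing
   maps), with ground truth for end-to-end validation, plus forward
   simulators for every acquisition so the fitters can be exercised from
   raw signals.

## Worked example

```r
library(wmsubtypes)

co  <- generatePhantomCohort(phantomSpec())   # 20 subjects, 7 maps, 7 missing
co
#> PhantomCohort: 20 subjects, 133 maps, grid 32x32x32, 3 planted components

res <- runPipeline("wm_run", cohort = co, orders = c(6, 8, 10, 12), seed = 17)
res$atlas
#> SubtypeAtlas: 3 subtypes (subtype1, subtype2, subtype3); thresholds z>=2 display / z>=3.2 extract, k>=200
#> Fleiss kappa:
#>   subtype threshold     kappa nRuns
#>  subtype1       2.0 0.9906028     4
#>  subtype1       3.2 0.9861955     4
#>  subtype2       2.0 0.9965085     4
#>  subtype2       3.2 0.9952409     4
#>  subtype3       2.0 0.9980657     4
#>  subtype3       3.2 0.9992535     4
```

Every decomposition between N = 6 and N = 12 finds the same three subtype
components (κ ≥ 0.99 at both thresholds). Their fingerprints, extracted
from the unsmoothed maps:

```r
fp  <- res$fingerprints
aggregate(fp[, c("R1","R2","AD","RD","chi_m","R2star","MPF")],
          list(subtype = fp$subtype), function(x) round(mean(x, na.rm = TRUE), 2))
#>  subtype   R1    R2      AD     RD  chi_m R2star   MPF
#> subtype1 1.02 16.47 1081.02 449.11 -11.05  21.71 12.25
#> subtype2 0.97 16.82  877.47 488.66  -6.68  20.28 12.36
#> subtype3 1.03 17.32  891.60 502.96  -2.53  20.85 13.10
```

subtype1 is the deep track-like class (largest AD and R2\*, most negative
χm, lowest MPF), subtype3 the frontal-subcortical class (highest MPF, R2
and χm), subtype2 the central-subcortical class in between — the planted
orderings. The cumulative Cohen's-d distances show the track-like subtype
far from both subcortical classes, which are much closer to each other:

```r
round(res$cohensD$distance, 2)
#> subtype1 vs subtype2 subtype1 vs subtype3 subtype2 vs subtype3
#>                11.35                12.62                 4.93
```

The phantom plants opposite-sign R1 aging slopes (decline in the
frontal-like class, increase elsewhere); the repeated-measures GLM
recovers the subtype × age interaction:

```r
subset(res$glm$perParameter, param == "R1" & term == "Type x Age")
#>  param       term        F df1 df2           p
#>     R1 Type x Age 5269.118   2  32 4.97788e-41
```

`runPipeline()` also writes the selection, κ, fingerprint and statistics
tables (TSV), and a `provenance.json` holding every threshold, the model
orders and the seed, to the output directory.

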