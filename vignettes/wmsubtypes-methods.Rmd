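---
title: "Models and methods behind wmsubtypes"
author: "wmsubtypes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmsubtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the signal models, the synthetic cohort generator,
the decomposition machinery and the statistical procedures implemented in
`wmsubtypes`, together with the numerical choices and their rationale. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

# Quantitative map fitting

All fitters operate voxelwise, are fully vectorized, and follow one error
convention: a voxel whose data cannot support the model (non-positive
magnitude, ratio outside the admissible branch, no sign change for a root
finder) is set to `NaN` and excluded downstream; malformed *inputs*
(too few echoes, rank-deficient gradient schemes, mismatched grids) raise
errors instead.

## R2* (multi-echo gradient echo)

Ordinary least squares of $\log S$ against echo time; the negative slope
is $R_2^*$ (s⁻¹), clipped at zero from below (a noiseless constant signal
must give exactly 0). Default echo times are 2.21–28.11 ms in 3.7 ms
steps (8 echoes); at least 3 echoes are required.

## B1 (actual flip-angle imaging)

The dual-TR AFI steady state gives $r = S_2/S_1 \approx
(1 + n\cos\theta)/(n + \cos\theta)$ with $n = TR_2/TR_1$ (default 5,
$TR_1 + TR_2 = 111$ ms, nominal angle 60°). The inversion
$\cos\theta = (rn-1)/(n-r)$ is applied on the physically valid branch;
$B_1$ is the actual-to-nominal angle ratio.

## B0 (two-echo phase difference)

$\Delta\phi$ between the two MT-image echoes (2.25 / 6.90 ms) is wrapped
to $(-\pi, \pi]$ and converted to Hz by $\Delta\phi / (2\pi\,\Delta TE)$.
The wrapping convention is a package choice; only offsets below
$1/(2\Delta TE) \approx 108$ Hz are unambiguous.

## R1 (two-point variable flip angle)

With $y_i = S_i/\sin\alpha_i$ and $x_i = S_i/\tan\alpha_i$ the SPGR
equation becomes linear with slope $E_1 = e^{-TR\cdot R_1}$; the two
B1-corrected angles (4°/25°, TR 20 ms) determine $E_1$ directly. Slopes
outside $(0,1)$ are invalid. Published corrections for incomplete RF
spoiling are protocol-specific polynomials, so the correction is exposed
as a pluggable function acting multiplicatively on the recovered T1, with
the identity as default; round-trip tests run with the identity.

## MPF (single-point two-pool magnetization transfer)

The MT-weighted/reference ratio is modeled by the steady state of a
two-pool system (free and macromolecular protons) under a repeated cycle:
off-resonance Gaussian saturation pulse (12 ms, 560°, 6 kHz), free
relaxation, instantaneous readout excitation (6°, acting on the free pool
only). Saturation uses the continuous-wave RMS approximation of the
pulse; the bound pool absorbs with a super-Lorentzian lineshape
($T_{2b} = 9.7$ µs), the free pool with a Lorentzian
($T_{2f} = 0.022\,T_1$). Exchange is constrained by
$k(1-f)/f = 19$ s⁻¹ and both pools share the measured $R_1$. The cycle
is an affine map propagated with closed-form 2×2 matrix exponentials, so
its fixed point is solved exactly per voxel; the ratio is independent of
M0 and receiver gain. The bound-pool fraction $f$ is recovered by
vectorized bisection on $f \in [0, 0.35]$ (40 halvings, i.e. ~1e-13 on
$f$, well inside the documented 1e-6 target); MPF = 100 f. B0 shifts the
effective offset and B1 scales both the saturation and readout angles.
The gap between pulse end and excitation (0.3 ms) is a sequence-timing
convention; the supplementary material of the source protocol does not
constrain it, and the ratio is insensitive to how the fixed TR is split.

## R2 (partially spoiled SSFP)

The ratio of two acquisitions differing only in the quadratic RF-spoiling
phase increment (1° — nearly coherent — and 20° — strongly spoiled;
TR 7 ms, 60°) retains T2 sensitivity. Rather than a truncated analytic
approximation, the package computes the exact steady state by Bloch
simulation of an isochromat ensemble (96 isochromats dephased by one
cycle per TR, 1200 repetitions, demodulated signal averaged over the
last 100), tabulates the ratio on a log-spaced T2 grid (4–600 ms) × B1
grid (0.8–1.2), and inverts it by monotone interpolation at the assumed
global T1 = 1.25 s. The table is cached per parameter set. Fitted T2 is
capped at 150 ms before conversion to R2 = 1/T2; ratios outside the
tabulated range are invalid voxels. Echo-time decay and off-resonance
precession cancel in the two-increment ratio and are not simulated. The
same tabulated relation serves as the forward model in the phantom
simulator, so round trips measure interpolation error only (≲0.1%);
the method's real-data T1-mismatch bias is a documented limitation, not
simulated.

## DTI scalars

Log-linear least squares of the six-component symmetric tensor over one
b = 0 volume and 20 quasi-uniform (Fibonacci-lattice) directions at
b = 1500 s/mm². Eigenvalues are sorted descending and clipped at zero
before the scalars (AD = λ₁, RD = (λ₂+λ₃)/2, ADC = mean, FA by the
normalized dispersion formula); clipping negative eigenvalues is a
package choice for noise robustness. Collinear gradient schemes are
rejected at the design-matrix rank check.

## R2′ and smoothing

R2′ = R2\* − R2 voxelwise; negative values (possible under noise) are
retained and counted in a QC attribute rather than clipped. Smoothing
uses the *discrete Gaussian* kernel $k_j = e^{-t} I_j(t)$ with
$t = \sigma_{vox}^2$ and $\sigma = \mathrm{FWHM}/2.3548$ per axis: it is
non-negative, sums to one (preserving constants and impulse mass), and is
exactly closed under convolution, so repeated smoothing composes like
true Gaussians — a property sampled continuous kernels lose badly at the
sub-voxel σ used here (5 mm FWHM on 2 mm voxels). Non-finite voxels are
excluded by normalized convolution, so NaNs neither spread nor bias
their neighbourhood; this also means maps are smoothed *within* the
brain mask, without bleeding the zero-filled exterior into the cortex
edge.

# The synthetic phantom cohort

The generator emulates the statistical structure the decomposition
assumes: three latent spatial components that combine linearly in each
voxel,

$$\mathrm{map}_{s,p}(v) = \mathrm{base}_p + \sum_c w_c(v)\,
(\mathrm{fp}_{c,p} - \mathrm{base}_p) + b_{s,p} + \text{covariates} +
\varepsilon,$$

with $w_c \in [0,1]$ smooth weight fields, subtype fingerprints
$\mathrm{fp}_{c,p}$ (defaults: the reference WM-subtype values, e.g.
AD 1066/863/859 µm²/s, MPF 12.4/13.8/12.8%), a grey-matter-like baseline,
a global per-(subject, parameter) offset $b_{s,p}$ with the reference
between-subject SDs, planted covariate effects and i.i.d. Gaussian map
noise. Defaults encode the study conditions: 20 subjects, 32³ voxels at
2 mm, ages uniform on 20–58 y, balanced gender, 7 missing maps (χm, R2\*
and MPF for two subjects, R1 for a third, so 20·7−7 = 133 maps), noise SD
at 20% of each parameter's between-subtype spread (the source data report
no map-level noise; this value keeps single-voxel noise visible while ROI
means stay fingerprint-dominated). Planted covariate structure: a global
negative MPF age slope (−0.035 %/y), opposite-sign R1 slopes
(−0.002 /y frontal-like, +0.002 /y elsewhere), and a female-positive
offset on track-like diffusivity (+25 µm²/s on AD and RD).

Geometry. An ellipsoidal brain with a logistic WM/GM transition; the WM
interior occupies ≈29% of the brain, a human-like proportion that also
keeps the chance-level WM overlap of noise components (~0.3) clearly
below the 0.5 selection cut. The three weight fields are anisotropic
Gaussians confined to WM, *flat-topped* (saturated at 1 over a core) and
*compactly supported* (weights < 0.08 truncated to 0): each component
therefore has a pure core where its fingerprint is attained exactly — the
operational meaning of extracting values "in their purest form" — and
distant tissue carries strictly zero weight. The builder enforces
pairwise spatial correlation ≤ 0.2 and ≤ 10% support overlap, and fails
loudly otherwise. Ground-truth "cores" additionally exclude any voxel
touched by another component.

What the phantom does **not** emulate: real anatomy and tract geometry,
spatially correlated (scanner) noise, registration and segmentation
error, partial-volume mixing beyond the planted overlap, B0/B1 spatial
structure (homogeneous by default; fields can be supplied to the raw-
signal simulator), susceptibility dipole physics (χm is drawn directly as
a parameter map), and T1 variation in the pSSFP forward model. Green
tests therefore demonstrate correctness of the pipeline under its own
generative assumptions — linear mixing, independent sources, Gaussian
noise — not performance on scanner data.

# Group decomposition

Normalization is at the *group* level (one mean/SD per parameter over all
subjects' in-brain voxels) to preserve between-subject variance, then
clamped to ±4 SD against outlier leverage. The group matrix keeps one row
per available map and only voxels finite in every row.

The spatial ICA is natural-gradient infomax with logistic nonlinearity on
PCA-whitened data: block updates (block ≈ √(V/3)), learning rate 0.01
annealed by 0.9 on oscillation, stopping when the relative weight change
drops below 1e-7 or after 512 passes, with up to 5 seeded restarts at
reduced rate on divergence. Sources are z-scored over the mask and
sign-fixed to non-negative skewness (a WM component is a localized
positive excursion, hence right-skewed); components are ordered by
variance explained. Model orders are configurable; on the bundled phantom
N ∈ {6, 8, 10, 12} plays the role that large orders play on a full
175-row cohort, scaled to the 133-row matrix.

Selection implements the two published criteria: the positive z ≥ 2
distribution must overlap WM (fraction of suprathreshold voxels with WM
probability > 0.5, at least 0.5 — both cuts configurable, as the source
describes the criterion only qualitatively), and the ratio of
between-parameter over between-subject loading SD must exceed 1.5 (an
ε = 1e-12 guards the denominator; the source gives no formula, so the
ratio is computed on parameter-wise and subject-wise mean loadings).

Matching across model orders maximizes total |spatial correlation| by an
exact assignment (subset dynamic programming; component counts are
small). The reference run is the smallest model order among runs with the
*modal* number of selected components: a single over-selecting run can
then not impose a spurious reference subtype (its extra component is
reported as unmatched). Matched pairs with r < 0.3 are flagged unstable.
Averaged subtype maps are re-standardized with the population SD (the
same convention the sources are z-scored with, so averaging identical
stacks is an exact identity). Fleiss' κ uses all analysis-mask voxels as
items (the alternative — only ever-flagged voxels — is a stricter,
smaller-denominator variant; the mask convention is the default).
Cluster-extent filtering (k ≥ 200 voxels, 26-connectivity) applies to
display maps only.

# Fingerprint statistics

Fingerprints come from *unsmoothed* maps inside the averaged-component
ROI (z ≥ 3.2) gated by the subject's WM probability (> 0.8); cells with
fewer than 10 eligible voxels or a missing map are NaN, and all tests use
casewise deletion. Paired t-tests run per parameter and subtype pair with
Bonferroni flags at α/m by default; the printed corrected cutoffs of the
source (0.011, 0.019) are not plain Bonferroni constants, so they are not
hard-coded — any explicit cutoff can be passed instead. Cohen's d uses
the averaged-variance pooled SD √((s₁²+s₂²)/2) (the pairs are the same
subjects, so group sizes are equal); relative contributions are |d|
normalized by the per-pair sum. Cross-correlations store the two
exploratory |r| tiers (0.38, 0.48) explicitly rather than re-deriving
them from α, because they encode the source's sample size.

The omnibus GLM is the multivariate repeated-measures decomposition:
between-subject terms (age, gender) are Wilks tests on subject-mean
responses over the 7 analysis parameters, F(7, n−9); within-subject terms
(type and its interactions) are Wilks tests on Helmert contrasts across
subtypes, F(14, n−16) — single-df hypotheses make the Wilks F exact, and
the H/E matrices are computed directly from the linear model. With the
default phantom, n = 17 complete subjects leaves the within tests with
df2 = 1; they are reported with their df, and planted-effect power is
carried by the per-parameter univariate repeated-measures models
(aov with a subject error stratum), whose type × age interaction on R1 is
the phantom analogue of the differential-aging result. Tract overlap is
the fraction of tract voxels inside each subtype's z > 2 region; rows may
sum above or below 1 by construction.

# Problem sizes and runtime choices

The bundled validation runs at desk scale: 32³ grids, 20 subjects,
N ≤ 12, 10 000-voxel Monte-Carlo noise checks, and 100 replicate cohorts
per GLM rate estimate; the full test suite runs in about two minutes and
the acceptance script in about 90 s on one CPU. The pSSFP table build
(~3 s) is cached per session. All stochastic steps are seeded, and the
cohort generator is byte-identical for a fixed spec and seed; RNG state
is always restored, so library calls do not perturb a caller's stream.

# Known limitations

- The pSSFP inversion assumes one global T1; true T1 spatial variation
  biases R2 in real data, and the phantom deliberately shares the
  assumption instead of modelling the bias.
- The MPF model uses the RMS continuous-wave approximation of the pulsed
  saturation; shaped-pulse transient effects are absorbed into the model
  definition (fit and forward simulation are the same model).
- Selection thresholds (WM overlap 0.5, ratio 1.5) are sharp cuts;
  components whose statistics sit at a threshold can flip across model
  orders, which the modal-reference matching absorbs but does not
  eliminate.
- The omnibus Wilks tests require complete 7-parameter data and lose
  severely in df on small cohorts with missing maps.
- Voxelwise inference, dual regression / back-reconstruction of
  subject-specific component maps, QSM reconstruction and spatial
  normalization are out of scope; maps must arrive co-registered in a
  common space.
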