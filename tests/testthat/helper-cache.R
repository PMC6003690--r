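## Expensive shared fixtures, built once per test run and reused across
## files (the default phantom cohort, its multi-order decomposition and the
## derived atlas/fingerprints).

.fixtures <- new.env(parent = emptyenv())

defaultCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generatePhantomCohort(phantomSpec())
  .fixtures$cohort
}

defaultGroupMatrix <- function() {
  if (is.null(.fixtures$gm)) {
    co <- defaultCohort()
    prep <- prepareMapsForDecomposition(co, groundTruth(co)$brainMask,
                                        fwhm_mm = 5)
    .fixtures$gm <- buildGroupMatrix(prep$records, groundTruth(co)$brainMask)
  }
  .fixtures$gm
}

## Selected component sets at model orders 6, 8, 10, 12 (seed 17 + N).
defaultRuns <- function() {
  if (is.null(.fixtures$runs)) {
    gm <- defaultGroupMatrix()
    gt <- groundTruth(defaultCohort())
    .fixtures$runs <- lapply(c(6L, 8L, 10L, 12L), function(N)
      selectWmComponents(runSpatialIca(gm, N, seed = 17L + N), gt$pWM))
  }
  .fixtures$runs
}

defaultAtlas <- function() {
  if (is.null(.fixtures$atlas)) {
    matched <- matchComponentsAcrossRuns(defaultRuns())
    .fixtures$atlas <- averageMatchedComponents(matched)
  }
  .fixtures$atlas
}

defaultFingerprints <- function() {
  if (is.null(.fixtures$fp))
    .fixtures$fp <- extractFingerprintTable(defaultAtlas(), defaultCohort())
  .fixtures$fp
}

## Map atlas subtype names to the ground-truth component they recover.
atlasTruthMatch <- function() {
  atlas <- defaultAtlas()
  gt <- groundTruth(defaultCohort())
  vi <- atlas@voxelIndex
  Z <- vapply(atlasZMaps(atlas), function(z) z[vi], numeric(length(vi)))
  W <- vapply(gt$weights, function(w) w[vi], numeric(length(vi)))
  R <- stats::cor(Z, W)
  list(match = colnames(R)[apply(R, 1, which.max)],
       r = apply(R, 1, max), R = R)
}

## A tiny noise-free spec (no noise, no subject effects, no covariates).
noiselessSpec <- function(n_subjects = 4L) {
  pars <- c("R1", "R2", "AD", "RD", "chi_m", "R2star", "MPF")
  zero3 <- matrix(0, 3, 7, dimnames = list(c("track", "frontal", "central"),
                                           pars))
  phantomSpec(n_subjects = n_subjects,
              subject_sd = stats::setNames(rep(0, 7), pars),
              noise_sd = stats::setNames(rep(0, 7), pars),
              age_slopes = zero3, gender_offsets = zero3,
              missing_entries = data.frame(subject = character(),
                                           param = character()))
}
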