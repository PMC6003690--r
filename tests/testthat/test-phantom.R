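test_that("component geometry respects overlap and correlation bounds", {
  geo <- buildComponentGeometry(phantomSpec())
  expect_length(geo$weights, 3L)
  ## weights are valid mixing fields
  for (w in geo$weights) expect_true(all(w >= 0 & w <= 1))
  expect_true(all(geo$pWM >= 0 & geo$pWM <= 1))
  ## pairwise spatial correlation over in-brain voxels
  W <- vapply(geo$weights, function(w) w[geo$brainMask],
              numeric(sum(geo$brainMask)))
  cc <- cor(W)
  expect_lt(max(cc[upper.tri(cc)]), 0.2)
  ## support overlap bounded at 10%
  for (i in 1:2) for (j in (i + 1):3) {
    si <- geo$weights[[i]] > 0.5; sj <- geo$weights[[j]] > 0.5
    expect_lte(sum(si & sj), 0.1 * min(sum(si), sum(sj)))
  }
  ## single-component spec: WM covers the field
  geo1 <- buildComponentGeometry(
    phantomSpec(fingerprints = phantomSpec()$fingerprints[1, , drop = FALSE]))
  expect_length(geo1$weights, 1L)
  expect_true(all(geo1$pWM[geo1$weights[[1]] > 0.5] > 0.5))
})

test_that("cohort generation is deterministic and counts maps correctly", {
  co1 <- defaultCohort()
  co2 <- generatePhantomCohort(phantomSpec())
  expect_identical(cohortRecords(co1)[[5]]@maps$MPF@data,
                   cohortRecords(co2)[[5]]@maps$MPF@data)
  expect_identical(cohortCovariates(co1), cohortCovariates(co2))
  ## 20 x 7 - 7 missing = 133 maps
  expect_identical(sum(vapply(cohortRecords(co1),
                              function(r) length(subjectMaps(r)),
                              integer(1))), 133L)
  ## exterior voxels are exactly zero
  gt <- groundTruth(co1)
  for (m in subjectMaps(cohortRecords(co1)[[1]]))
    expect_true(all(mapData(m)[!gt$brainMask] == 0))
})

test_that("degenerate mixing reproduces fingerprints exactly in pure cores", {
  co <- generatePhantomCohort(noiselessSpec())
  gt <- groundTruth(co)
  spec <- co@spec
  for (ci in 1:3) {
    pure <- gt$weights[[ci]] > 1 - 1e-12
    ## only voxels where no other component contributes
    for (cj in setdiff(1:3, ci)) pure <- pure & gt$weights[[cj]] == 0
    expect_gt(sum(pure), 0)
    for (p in spec$params) {
      vals <- mapData(subjectMaps(cohortRecords(co)[[1]])[[p]])[pure]
      expect_equal(unname(vals), rep(spec$fingerprints[ci, p], sum(pure)),
                   tolerance = 1e-12)
    }
  }
})

test_that("planted fingerprint means and subject variability are faithful", {
  co <- defaultCohort()
  gt <- groundTruth(co)
  spec <- co@spec
  ## expected track AD includes the balanced-gender mean of the offset
  expAD <- spec$fingerprints["track", "AD"] +
    0.5 * spec$gender_offsets["track", "AD"]
  v <- vapply(cohortRecords(co), function(r)
    if ("AD" %in% names(subjectMaps(r)))
      mean(mapData(subjectMaps(r)$AD)[gt$cores$track]) else NA_real_,
    numeric(1))
  se <- sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  expect_lt(abs(mean(v, na.rm = TRUE) - expAD), 2 * se + 2)
  ## empirical between-subject SD within 25% of the spec at n = 20
  for (p in c("AD", "MPF", "R2star")) {
    vv <- vapply(cohortRecords(co), function(r)
      if (p %in% names(subjectMaps(r)))
        mean(mapData(subjectMaps(r)[[p]])[gt$cores$track]) else NA_real_,
      numeric(1))
    ## remove the planted covariate trend before comparing SDs
    cov <- cohortCovariates(co)
    keep <- is.finite(vv)
    res <- resid(lm(vv[keep] ~ cov$age[keep] + cov$gender[keep]))
    expect_lt(abs(sd(res) - spec$subject_sd[p]), 0.25 * spec$subject_sd[p] +
                3 * spec$noise_sd[p] / sqrt(sum(gt$cores$track)))
  }
})

test_that("missing-entry injection removes maps and flags empty subjects", {
  co <- generatePhantomCohort(noiselessSpec())
  ## drop one map
  co1 <- injectMissingEntries(co, data.frame(subject = "s01", param = "MPF"))
  expect_length(subjectMaps(cohortRecords(co1)[[1]]), 6L)
  expect_false("MPF" %in% names(subjectMaps(cohortRecords(co1)[[1]])))
  ## drop nothing is the identity
  co2 <- injectMissingEntries(co, data.frame(subject = character(),
                                             param = character()))
  expect_identical(cohortRecords(co2), cohortRecords(co))
  ## unknown entry is rejected
  expect_error(injectMissingEntries(co, data.frame(subject = "s01",
                                                   param = "XX")),
               "unknown missing entry")
  ## dropping all maps flags the subject unusable
  all7 <- data.frame(subject = "s02", param = co@spec$params)
  co3 <- injectMissingEntries(co, all7)
  expect_identical(groundTruth(co3)$unusableSubjects, "s02")
})

test_that("tract fixtures route through the intended territories", {
  co <- defaultCohort()
  gt <- groundTruth(co)
  tr <- gt$tracts
  ## crossing tract intersects both the track and frontal territories
  expect_gt(sum(tr$crossing & gt$weights$track > 0.5), 0)
  expect_gt(sum(tr$crossing & gt$weights$frontal > 0.5), 0)
  ## confined tract stays inside the track territory
  expect_true(all(gt$weights$track[tr$confined] > 0.3))
  expect_identical(sum(tr$confined & gt$weights$frontal > 0.5), 0L)
  ## deterministic
  tr2 <- makeTractFixtures(phantomSpec())
  expect_identical(tr, tr2)
})

test_that("simulated raw signals round-trip through the fitters", {
  co <- generatePhantomCohort(noiselessSpec(n_subjects = 2L))
  rec <- cohortRecords(co)[[1]]
  gt <- groundTruth(co)
  raw <- simulateRawSignals(rec)
  brain <- gt$brainMask
  ## R2*: voxelwise match to truth
  fit <- fitR2Star(raw$mgre$stack, raw$mgre$params)
  truth <- mapData(subjectMaps(rec)$R2star)
  err <- abs(mapData(fit$R2star)[brain] - truth[brain]) /
    pmax(truth[brain], 1)
  expect_lt(max(err), 1e-6)
  ## exterior stays zero in every emitted volume
  for (e in seq_len(dim(raw$mgre$stack)[4]))
    expect_true(all(raw$mgre$stack[, , , e][!brain] == 0))
  expect_true(all(raw$vfa$s_low[!brain] == 0))
  expect_true(all(raw$dti$dwi[, , , 3][!brain] == 0))
  ## B1 = 0.9 field: uncorrected fit is biased, corrected is exact
  b1f <- array(0.9, dim(brain))
  raw9 <- simulateRawSignals(rec, sequences = "vfa", b1_field = b1f)
  r1true <- mapData(subjectMaps(rec)$R1)
  r1nc <- fitR1Vfa(raw9$vfa$s_low, raw9$vfa$s_high, raw9$vfa$params)
  r1c <- fitR1Vfa(raw9$vfa$s_low, raw9$vfa$s_high, raw9$vfa$params, b1 = b1f)
  biasNc <- abs(mapData(r1nc)[brain] - r1true[brain]) / r1true[brain]
  biasC <- abs(mapData(r1c)[brain] - r1true[brain]) / r1true[brain]
  expect_gt(median(biasNc, na.rm = TRUE), 0.02)
  expect_lt(max(biasC, na.rm = TRUE), 1e-6)
  ## MPF pair inverts back to the planted MPF map
  mp <- fitMpfSinglePoint(raw$mt$mt_img, raw$mt$ref_img,
                          r1 = subjectMaps(rec)$R1)
  mtruth <- mapData(subjectMaps(rec)$MPF)
  expect_lt(max(abs(mapData(mp)[brain] - mtruth[brain])), 0.05)
  ## missing prerequisite map: sequence skipped with a warning
  rec2 <- cohortRecords(injectMissingEntries(
    co, data.frame(subject = "s01", param = "R2star")))[[1]]
  expect_warning(out <- simulateRawSignals(rec2, sequences = "mgre"),
                 "skipping")
  expect_null(out$mgre)
})
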