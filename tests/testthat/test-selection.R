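test_that("parameter/subject loading-SD ratio separates shared from
           subject-driven components", {
  ri <- data.frame(subject = rep(sprintf("s%02d", 1:20), each = 7),
                   param = rep(c("R1", "R2", "AD", "RD", "chi_m", "R2star",
                                 "MPF"), 20))
  ## constant across subjects, varying across parameters
  lp <- as.numeric(factor(ri$param))
  expect_gte(paramSubjectRatio(lp, ri), 10)
  ## varying only across subjects
  ls <- as.numeric(factor(ri$subject))
  expect_lt(paramSubjectRatio(ls, ri), 0.01)
  ## single-subject artifact: loadings concentrated on one subject
  la <- as.numeric(ri$subject == "s05")
  expect_lt(paramSubjectRatio(la, ri), 1.5)
  ## undefined with fewer than 2 parameters or subjects
  expect_true(is.na(paramSubjectRatio(1:3,
    data.frame(subject = c("a", "b", "c"), param = rep("R1", 3)))))
})

test_that("planted components pass, artifacts fail the selection rules", {
  runs <- defaultRuns()
  gt <- groundTruth(defaultCohort())
  ## exactly 3 selected at every model order on the default phantom
  expect_identical(vapply(runs, function(r) nrow(componentStats(r)),
                          integer(1)), rep(3L, 4L))
  for (r in runs) {
    expect_true(all(componentStats(r)$ratio > 1.5))
    expect_true(all(componentStats(r)$wmOverlap >= 0.5))
  }
  ## ratio_min = Inf empties the selection
  gm <- defaultGroupMatrix()
  cs <- runSpatialIca(gm, 6, seed = 23)
  none <- selectWmComponents(cs, gt$pWM, ratioMin = Inf)
  expect_identical(nrow(componentStats(none)), 0L)
})

test_that("a component with no positive WM voxels is rejected", {
  ## synthetic ComponentSet: one source peaked outside WM, one inside
  gm <- defaultGroupMatrix()
  gt <- groundTruth(defaultCohort())
  cs <- runSpatialIca(gm, 6, seed = 23)
  wmv <- gt$pWM[cs@voxelIndex]
  fake <- cs
  ## replace the first source by one whose z >= 2 voxels all lie in GM
  src <- componentSources(fake)
  gmvox <- which(wmv < 0.2)
  z <- rnorm(length(wmv), -0.2, 0.5)
  z[gmvox[1:300]] <- 4
  src[1, ] <- (z - mean(z)) / sd(z)
  fake@sources <- src
  ov <- componentWmOverlap(fake, gt$pWM)
  expect_lt(ov[1], 0.5)
  sel <- selectWmComponents(fake, gt$pWM)
  expect_false(1L %in% componentStats(sel)$component)
})

test_that("a planted subject-specific artifact source is not selected", {
  ## inject a strong single-subject spatial source into the group matrix
  gm <- defaultGroupMatrix()
  gt <- groundTruth(defaultCohort())
  X <- matrixData(gm)
  withr::with_seed(41, {
    blob <- exp(-(seq_len(ncol(X)) %% 97 - 48)^2 / 50)  # arbitrary pattern
  })
  rows <- which(rowIndex(gm)$subject == "s07")
  X[rows, ] <- X[rows, ] + 8 * matrix(blob, length(rows), ncol(X),
                                      byrow = TRUE)
  gm2 <- new("GroupMatrix", data = X, rowIndex = rowIndex(gm),
             voxelIndex = gm@voxelIndex, gridDim = gm@gridDim,
             mask = gm@mask)
  cs <- runSpatialIca(gm2, 8, seed = 5)
  ## find the artifact component (max loading concentration on s07)
  conc <- apply(componentLoadings(cs), 2, function(l)
    sum(abs(l[rows])) / sum(abs(l)))
  art <- which.max(conc)
  expect_gt(conc[art], 0.5)
  expect_lt(componentStats(cs)$ratio[art], 1.5)
})
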