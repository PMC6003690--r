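## small helper: records with hand-built maps on a tiny grid
tinyRecords <- function(values, d = c(4, 4, 4)) {
  lapply(seq_along(values), function(i) {
    maps <- lapply(names(values[[i]]), function(p)
      ParameterMap(array(values[[i]][[p]], d), p, sprintf("s%02d", i)))
    SubjectRecord(sprintf("s%02d", i), maps,
                  pWM = array(1, d), pGM = array(0, d))
  })
}

test_that("group normalization centers, scales and clamps per parameter", {
  d <- c(4, 4, 4)
  mask <- array(TRUE, d)
  withr::with_seed(21, {
    recs <- tinyRecords(list(list(R1 = rnorm(64, 1, 0.1)),
                             list(R1 = rnorm(64, 1.2, 0.1))), d)
  })
  out <- normalizeGroupIntensity(recs, mask)
  vals <- c(mapData(subjectMaps(out$records[[1]])$R1),
            mapData(subjectMaps(out$records[[2]])$R1))
  expect_lt(abs(mean(vals)), 1e-9)
  expect_equal(sd(vals), 1, tolerance = 1e-9)  # sd 1 (no value hit the clamp)
  ## clamp rule: values beyond +-4 group SD map to exactly +-4
  withr::with_seed(22, v1 <- rnorm(64, 10))
  v1[1] <- 10 + 50   # far outlier
  mu <- mean(c(v1, v1)); s <- sd(c(v1, v1))
  expect_gt((v1[1] - mu) / s, 4)   # genuinely beyond the clamp
  recs <- tinyRecords(list(list(R2 = v1), list(R2 = v1)), d)
  out <- normalizeGroupIntensity(recs, mask)
  zt <- mapData(subjectMaps(out$records[[1]])$R2)
  expect_equal(unname(zt[1]), 4)
  ## identical input maps give identical scaled maps
  expect_identical(mapData(subjectMaps(out$records[[1]])$R2),
                   mapData(subjectMaps(out$records[[2]])$R2))
  ## zero group SD is rejected
  recs <- tinyRecords(list(list(MPF = rep(7, 64)), list(MPF = rep(7, 64))), d)
  expect_error(normalizeGroupIntensity(recs, mask), "zero group SD")
  ## a parameter present for fewer than 2 subjects is rejected
  recs <- tinyRecords(list(list(R1 = rnorm(64, 10)),
                           list(R2 = rnorm(64, 10))), d)
  expect_error(normalizeGroupIntensity(recs, mask), "fewer than 2")
})

test_that("group matrix rows count available maps only", {
  ## default phantom: 20 x 7 - 7 = 133 rows
  gm <- defaultGroupMatrix()
  expect_identical(nrow(matrixData(gm)), 133L)
  expect_identical(nrow(rowIndex(gm)), 133L)
  expect_false(anyNA(matrixData(gm)))
  ## the reference cohort bookkeeping: 26 x 7 - 7 = 175 rows
  d <- c(3, 3, 3)
  pars <- c("R1", "R2", "AD", "RD", "chi_m", "R2star", "MPF")
  recs <- lapply(1:26, function(i) {
    maps <- lapply(pars, function(p)
      ParameterMap(array(rnorm(27, 10), d), p, sprintf("s%02d", i)))
    SubjectRecord(sprintf("s%02d", i), maps, array(1, d), array(0, d))
  })
  drop7 <- data.frame(subject = c("s01", "s01", "s01", "s02", "s02", "s02",
                                  "s03"),
                      param = c("chi_m", "R2star", "MPF",
                                "chi_m", "R2star", "MPF", "R1"))
  for (k in seq_len(nrow(drop7)))
    recs[[match(drop7$subject[k], sprintf("s%02d", 1:26))]]@maps[[drop7$param[k]]] <- NULL
  gm26 <- buildGroupMatrix(recs, array(TRUE, d))
  expect_identical(nrow(matrixData(gm26)), 175L)
  ## empty mask rejected
  expect_error(buildGroupMatrix(recs, array(FALSE, d)), "empty")
})

test_that("unfolding then folding a row restores the map on the mask", {
  gm <- defaultGroupMatrix()
  co <- defaultCohort()
  vol <- foldRow(gm, 1)
  src <- rowIndex(gm)[1, ]
  rec <- cohortRecords(co)[[match(src$subject,
                                  vapply(cohortRecords(co), subjectId,
                                         character(1)))]]
  expect_true(src$param %in% names(subjectMaps(rec)))
  ## values on the mask equal the matrix row exactly
  expect_identical(vol[gm@voxelIndex], matrixData(gm)[1, ])
  expect_true(all(is.na(vol[!gm@mask])))
})
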