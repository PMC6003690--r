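test_that("fingerprint extraction recovers planted values on a noise-free
           cohort", {
  co <- generatePhantomCohort(noiselessSpec())
  gt <- groundTruth(co)
  tab <- extractFingerprintTable(gt$cores, co)
  spec <- co@spec
  for (cn in rownames(spec$fingerprints)) for (p in spec$params) {
    v <- tab[tab$subtype == cn, p]
    expect_lt(max(abs(v - spec$fingerprints[cn, p])) /
                abs(spec$fingerprints[cn, p]), 0.01)
  }
  ## pWM column reflects the gate
  expect_true(all(tab$pWM > 0.8))
})

test_that("missing maps yield NaN cells without disturbing others", {
  co <- defaultCohort()
  gt <- groundTruth(co)
  tab <- extractFingerprintTable(gt$cores, co)
  s01 <- tab[tab$subject == "s01", ]
  expect_true(all(is.nan(s01$MPF)))
  expect_true(all(is.finite(s01$AD)))
  ## an impossible WM gate empties the table with a warning
  expect_warning(bad <- extractFingerprintTable(gt$cores, co,
                                                wm_p_min = 1.01),
                 "all-NaN")
  expect_true(all(is.nan(bad$AD)))
  ## an atlas with empty ROIs is rejected
  empty <- list(a = array(FALSE, dim(gt$pWM)))
  expect_error(extractFingerprintTable(empty, co), "rejected")
})

test_that("paired subtype tests match the textbook formula", {
  ## synthetic pair with a known shift
  withr::with_seed(61, {
    x <- rnorm(20, 10, 2)
    y <- x + rnorm(20, 2, 1)
  })
  tab <- data.frame(subject = rep(sprintf("s%02d", 1:20), 2),
                    subtype = rep(c("A", "B"), each = 20),
                    AD = c(x, y))
  res <- pairedSubtypeTests(tab, params = "AD")
  d <- x - y
  tRef <- mean(d) / (sd(d) / sqrt(20))
  pRef <- 2 * pt(-abs(tRef), 19)
  expect_equal(res$t, tRef, tolerance = 1e-10)
  expect_equal(res$p, pRef, tolerance = 1e-10)
  expect_identical(res$df, 19)
  ## identical columns: t = 0, p = 1
  tab0 <- tab; tab0$AD <- rep(x, 2)
  res0 <- pairedSubtypeTests(tab0, params = "AD")
  expect_identical(res0$t, 0)
  expect_identical(res0$p, 1)
  ## constant nonzero difference: p at the machine floor
  tabc <- tab; tabc$AD <- c(x, x + 2)
  resc <- pairedSubtypeTests(tabc, params = "AD")
  expect_identical(resc$p, .Machine$double.xmin)
  expect_true(resc$significant)
  ## fewer than 3 complete pairs
  tabs <- tab[tab$subject %in% c("s01", "s02"), ]
  expect_warning(ress <- pairedSubtypeTests(tabs, params = "AD"),
                 "fewer than 3")
  expect_true(is.na(ress$p))
})

test_that("Cohen's d ledger reproduces the reference AD effect size", {
  ## track vs frontal AD: 1066 +- 40 vs 863 +- 22
  expect_equal(round(cohensD(1066, 40, 863, 22), 2), 6.29)
  ## contributions sum to one per pair
  withr::with_seed(62, {
    tab <- data.frame(subject = rep(sprintf("s%02d", 1:15), 3),
                      subtype = rep(c("A", "B", "C"), each = 15),
                      AD = rnorm(45, rep(c(1066, 863, 859), each = 15), 30),
                      MPF = rnorm(45, rep(c(12.4, 13.8, 12.8), each = 15), 0.4))
  })
  led <- cohensDContributions(tab, params = c("AD", "MPF"))
  agg <- tapply(led$d$contribution, led$d$pair, sum)
  expect_true(all(abs(agg - 1) < 1e-9))
  ## identical groups: zero d, zero distance, undefined contributions
  tab2 <- tab; tab2$AD <- rep(tab$AD[1:15], 3); tab2$MPF <- rep(tab$MPF[1:15], 3)
  led2 <- cohensDContributions(tab2, params = c("AD", "MPF"))
  expect_true(all(led2$d$d == 0))
  expect_true(all(led2$distance == 0))
  expect_true(all(is.nan(led2$d$contribution)))
})

test_that("cross-correlation matrices carry the two significance tiers", {
  withr::with_seed(63, {
    x <- rnorm(24)
    tab <- data.frame(subject = sprintf("s%02d", 1:24), subtype = "A",
                      AD = x, RD = -x, MPF = x + rnorm(24, 0, 1e-8))
  })
  cc <- crossCorrelationMatrix(tab, params = c("AD", "RD", "MPF"))
  expect_equal(cc$A$r["AD", "MPF"], 1, tolerance = 1e-6)
  expect_equal(cc$A$r["AD", "RD"], -1, tolerance = 1e-12)
  expect_identical(cc$A$tier["AD", "RD"], 2L)
  expect_identical(attr(cc, "rTiers"), c(0.38, 0.48))
})

test_that("sample correlation is estimated with the expected small-sample
           bias", {
  ## bivariate normal rho = 0.7, n = 24: E[r] ~ 0.69 over many replicates
  withr::with_seed(64, {
    rhat <- replicate(1000, {
      x <- rnorm(24)
      y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(24)
      cor(x, y)
    })
  })
  expect_lt(abs(mean(rhat) - 0.69), 0.03)
})

test_that("tract overlap proportions are computed against suprathreshold
           maps", {
  d <- c(10, 10, 10)
  z1 <- array(-1, d); z1[2:5, 2:5, 2:5] <- 5
  z2 <- array(-1, d)
  tract_in <- array(FALSE, d); tract_in[3:4, 3:4, 3:4] <- TRUE
  tract_out <- array(FALSE, d); tract_out[8:9, 8:9, 8:9] <- TRUE
  ov <- tractOverlapProportions(list(A = z1, B = z2),
                                list(inside = tract_in, outside = tract_out))
  expect_identical(ov["inside", "A"], 1)
  expect_identical(ov["inside", "B"], 0)
  expect_true(all(ov["outside", ] == 0))
  expect_error(tractOverlapProportions(list(A = z1),
                                       list(bad = array(FALSE, d))), "empty")
  ## phantom fixtures: the crossing tract loads on two subtypes
  atlas <- defaultAtlas()
  gt <- groundTruth(defaultCohort())
  po <- tractOverlapProportions(atlas, gt$tracts)
  mt <- atlasTruthMatch()
  colnames(po) <- mt$match[match(colnames(po), names(atlasZMaps(atlas)))]
  expect_gt(po["crossing", "track"], 0.2)
  expect_gt(po["crossing", "frontal"], 0.2)
  ## the confined tract concentrates on the track subtype
  expect_gt(po["confined", "track"], 0.8)
  expect_lt(max(po["confined", c("frontal", "central")]), 0.05)
})
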