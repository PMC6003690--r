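te8 <- seq(2.21, by = 3.7, length.out = 8)

test_that("R2* log-linear fit recovers decay rates and flags bad voxels", {
  ## zero decay identity
  st <- array(100, c(2, 2, 2, 8))
  fit <- fitR2Star(st, mgreParams(te8))
  expect_equal(unname(mapData(fit$R2star)[1, 1, 1]), 0)
  ## exact recovery of a known rate at the protocol echo times
  truth <- 21.7
  sig <- 100 * exp(-truth * te8 / 1000)
  st <- array(rep(sig, each = 8), c(2, 2, 2, 8))
  fit <- fitR2Star(st, mgreParams(te8))
  expect_lt(max(abs(mapData(fit$R2star) - truth)) / truth, 1e-9)
  expect_lt(max(abs(mapData(fit$S0) - 100)) / 100, 1e-9)
  ## non-positive in-mask signal becomes NaN, not an error
  st[1, 1, 1, 3] <- 0
  fit <- fitR2Star(st, mgreParams(te8))
  expect_true(is.nan(mapData(fit$R2star)[1, 1, 1]))
  expect_false(anyNA(mapData(fit$R2star)[2, , ]))
  ## fewer than 3 echoes is rejected
  expect_error(fitR2Star(array(1, c(2, 2, 2, 2)),
                         mgreParams(c(2, 5))), "3 echoes")
})

test_that("R2* estimate is unbiased at SNR 100 (Monte Carlo)", {
  nv <- 10000L
  truth <- 21.7
  withr::with_seed(11, {
    sig <- matrix(rep(100 * exp(-truth * te8 / 1000), each = nv), nv) +
      matrix(rnorm(nv * 8), nv)
  })
  fit <- fitR2Star(array(sig, c(nv, 1, 1, 8)), mgreParams(te8))
  bias <- abs(mean(mapData(fit$R2star), na.rm = TRUE) - truth) / truth
  expect_lt(bias, 0.02)
})

test_that("AFI inversion returns the actual-to-nominal flip angle ratio", {
  ## closed-form forward values for B1 = 1 and B1 = 1.2 at 60 deg, n = 5
  expect_equal(afiSignalRatio(60, 5), 3.5 / 5.5, tolerance = 1e-12)
  expect_equal(afiSignalRatio(72, 5), 0.47940, tolerance = 1e-4)
  d <- c(2, 2, 2)
  for (b1true in c(1, 1.2)) {
    r <- afiSignalRatio(60 * b1true, 5)
    b1 <- fitB1Afi(array(1, d), array(r, d), afiParams())
    expect_equal(unname(mapData(b1)[1, 1, 1]), b1true, tolerance = 1e-6)
  }
  ## degenerate background voxel
  b1 <- fitB1Afi(array(0, d), array(0, d), afiParams())
  expect_true(all(is.nan(mapData(b1))))
})

test_that("B0 phase-difference fit wraps phase to (-pi, pi]", {
  d <- c(2, 2, 1)
  z <- array(0, d)
  expect_equal(unname(mapData(fitB0FromPhase(z, z))[1]), 0)
  ## delta-phi = pi over the default 4.65 ms echo spacing
  b0 <- fitB0FromPhase(z, array(pi, d))
  expect_equal(unname(mapData(b0)[1]), 1 / (2 * 4.65e-3), tolerance = 1e-9)
  ## phase periodicity
  b0a <- fitB0FromPhase(z, array(0.1, d))
  b0b <- fitB0FromPhase(z, array(2 * pi + 0.1, d))
  expect_equal(mapData(b0a), mapData(b0b), tolerance = 1e-12)
  expect_error(fitB0FromPhase(z, z, mtParams(te_pair_ms = c(2, 2))),
               "delta TE")
})

test_that("VFA two-point fit inverts the SPGR equation with B1 correction", {
  d <- c(2, 2, 1)
  pr <- vfaParams()
  ## grid spanning the reference WM range; 1.07 s^-1 anchors frontal WM R1
  for (t1 in c(0.5, 1 / 1.07, 1.0, 2.0)) {
    lo <- array(spgrSignal(t1, 20, 4), d)
    hi <- array(spgrSignal(t1, 20, 25), d)
    r1 <- fitR1Vfa(lo, hi, pr)
    expect_lt(abs(mapData(r1)[1] - 1 / t1) * t1, 1e-9)
  }
  ## B1-corrected angles reproduce the same R1
  b1 <- array(0.9, d)
  lo <- array(spgrSignal(1, 20, 4 * 0.9), d)
  hi <- array(spgrSignal(1, 20, 25 * 0.9), d)
  r1 <- fitR1Vfa(lo, hi, pr, b1 = b1)
  expect_equal(unname(mapData(r1)[1]), 1, tolerance = 1e-9)
  ## signals inconsistent with any E1 in (0, 1) -> NaN
  r1 <- fitR1Vfa(array(0.01, d), array(1, d), pr)
  expect_true(all(is.nan(mapData(r1))))
  ## spoiling correction hook acts multiplicatively on T1
  r1c <- fitR1Vfa(array(spgrSignal(1, 20, 4), d),
                  array(spgrSignal(1, 20, 25), d), pr,
                  spoilingCorrection = function(t1) 1.1 * t1)
  expect_equal(unname(mapData(r1c)[1]), 1 / 1.1, tolerance = 1e-9)
})

test_that("VFA estimate is unbiased at SNR 100 (Monte Carlo)", {
  nv <- 10000L
  s1 <- spgrSignal(1 / 1.07, 20, 4); s2 <- spgrSignal(1 / 1.07, 20, 25)
  withr::with_seed(12, {
    lo <- array(s1 * (1 + rnorm(nv) / 100), c(nv, 1, 1))
    hi <- array(s2 * (1 + rnorm(nv) / 100), c(nv, 1, 1))
  })
  r1 <- fitR1Vfa(lo, hi)
  expect_lt(abs(mean(mapData(r1), na.rm = TRUE) - 1.07) / 1.07, 0.02)
})

test_that("pSSFP ratio inversion recovers T2 and applies the 150 ms cap", {
  d <- c(1, 1, 1)
  pr <- pssfpParams()
  ## round trips across the WM range; 58 ms anchors central WM R2 = 17.2
  for (t2ms in c(40, 1000 / 17.2, 60, 120)) {
    s1 <- pssfpSignal(t2ms / 1000, 1.25, 60, 7, 1)
    s2 <- pssfpSignal(t2ms / 1000, 1.25, 60, 7, 20)
    r2 <- fitR2Pssfp(array(s1, d), array(s2, d), pr)
    expect_lt(abs(1000 / mapData(r2)[1] - t2ms) / t2ms, 0.01)
  }
  ## long T2 capped at 150 ms -> R2 = 6.67 s^-1
  s1 <- pssfpSignal(0.4, 1.25, 60, 7, 1)
  s2 <- pssfpSignal(0.4, 1.25, 60, 7, 20)
  r2 <- fitR2Pssfp(array(s1, d), array(s2, d), pr)
  expect_equal(unname(mapData(r2)[1]), 1 / 0.15, tolerance = 1e-9)
  ## inadmissible ratio -> NaN
  r2 <- fitR2Pssfp(array(1, d), array(2, d), pr)   # ratio 0.5 < min
  expect_true(is.nan(mapData(r2)[1]))
})

test_that("pSSFP estimate is unbiased at SNR 100 (Monte Carlo)", {
  nv <- 10000L
  t2 <- 1 / 17.2
  s1 <- pssfpSignal(t2, 1.25, 60, 7, 1)
  s2 <- pssfpSignal(t2, 1.25, 60, 7, 20)
  withr::with_seed(13, {
    a <- array(s1 * (1 + rnorm(nv) / 100), c(nv, 1, 1))
    b <- array(s2 * (1 + rnorm(nv) / 100), c(nv, 1, 1))
  })
  r2 <- fitR2Pssfp(a, b)
  expect_lt(abs(mean(mapData(r2), na.rm = TRUE) - 17.2) / 17.2, 0.02)
})

test_that("R2' is the voxelwise difference of R2* and R2", {
  d <- c(2, 2, 2)
  ## frontal-WM column of the reference fingerprint table
  r2s <- ParameterMap(array(21.1, d), "R2star", "s1")
  r2 <- ParameterMap(array(17.9, d), "R2", "s1")
  r2p <- deriveR2Prime(r2s, r2)
  expect_equal(unname(mapData(r2p)[1]), 3.2, tolerance = 1e-12)
  ## identical inputs give a zero map
  expect_true(all(mapData(deriveR2Prime(r2, r2)) == 0))
  ## algebraic identity on random maps, negatives retained and counted
  withr::with_seed(3, {
    a <- ParameterMap(array(rnorm(8, 20), d), "R2star", "s1")
    b <- ParameterMap(array(rnorm(8, 18), d), "R2", "s1")
  })
  dm <- deriveR2Prime(a, b)
  expect_equal(mapData(dm) + mapData(b), mapData(a), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(mapData(dm), "nNegative"), sum(mapData(dm) < 0))
  ## grid mismatch and subject mismatch are rejected
  expect_error(deriveR2Prime(r2s, ParameterMap(array(1, c(3, 3, 3)), "R2", "s1")),
               "mismatch")
  expect_error(deriveR2Prime(r2s, ParameterMap(array(1, d), "R2", "s2")),
               "subject")
})

test_that("Gaussian smoothing preserves constants, mass and the semigroup", {
  d <- c(32, 32, 32)
  ## constant volume unchanged at interior voxels
  v <- smoothVolume(array(7, d), 5, voxelSize = 2)
  expect_lt(max(abs(v[8:24, 8:24, 8:24] - 7)), 1e-9)
  ## delta impulse: kernel mass sums to 1
  imp <- array(0, d); imp[16, 16, 16] <- 1
  sm <- smoothVolume(imp, 5, voxelSize = 2)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  ## two 3-mm smooths equal one sqrt(18)-mm smooth
  s2x <- smoothVolume(smoothVolume(imp, 3, 2), 3, 2)
  s1x <- smoothVolume(imp, sqrt(18), 2)
  expect_lt(max(abs(s2x - s1x)), 1e-6)
  ## fwhm 0 is the identity
  expect_identical(smoothVolume(imp, 0, 2), imp)
})
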