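## Relaxometry and field-map fitters. All fitters are voxelwise, vectorized,
## and mark unrecoverable voxels as NaN rather than raising.

#' Fit R2* by log-linear regression over echoes
#'
#' Ordinary least squares of log signal against echo time per voxel; the
#' negative slope is R2*, clipped at zero from below. Voxels with
#' non-positive or non-finite signal at any echo become NaN.
#'
#' @param echo_stack 4D array (x, y, z, echo) of magnitude signals.
#' @param params an [mgreParams()] descriptor (>= 3 echoes required).
#' @param subjectId,voxelSize passed to the output [ParameterMap()].
#' @return list with elements `R2star` and `S0` (ParameterMap objects).
#' @export
fitR2Star <- function(echo_stack, params = mgreParams(),
                      subjectId = "unknown", voxelSize = 2) {
  d <- dim(echo_stack)
  if (length(d) != 4L) stop("echo_stack must be 4D (x, y, z, echo)")
  ne <- d[4]
  if (ne < 3L) stop("at least 3 echoes are required")
  if (length(params$echo_times_ms) != ne)
    stop("echo count does not match params$echo_times_ms")
  te <- params$echo_times_ms / 1000
  S <- matrix(echo_stack, ncol = ne)
  ok <- rowSums(!is.finite(S) | S <= 0) == 0L
  y <- log(S[ok, , drop = FALSE])
  tc <- te - mean(te)
  slope <- (y %*% tc) / sum(tc^2)
  inter <- rowMeans(y) - slope * mean(te)
  r2s <- rep(NaN, nrow(S)); s0 <- rep(NaN, nrow(S))
  r2s[ok] <- pmax(-slope, 0)
  s0[ok] <- exp(inter)
  list(R2star = ParameterMap(array(r2s, d[1:3]), "R2star", subjectId, voxelSize),
       S0 = ParameterMap(array(s0, d[1:3]), "S0", subjectId, voxelSize))
}

#' Fit the relative transmit field B1 from an AFI pair
#'
#' Inverts r = S2/S1 = (1 + n cos(theta))/(n + cos(theta)) for the actual
#' flip angle; B1 = theta_actual / theta_nominal. Voxels where the ratio
#' leaves the physically valid branch become NaN.
#'
#' @param s1,s2 3D volumes acquired at TR1 and TR2.
#' @param params an [afiParams()] descriptor.
#' @inheritParams fitR2Star
#' @return a B1 [ParameterMap()].
#' @export
fitB1Afi <- function(s1, s2, params = afiParams(),
                     subjectId = "unknown", voxelSize = 2) {
  stopIfGridMismatch(s1, s2, "AFI volumes")
  n <- params$n
  r <- s2 / s1
  ca <- (r * n - 1) / (n - r)
  bad <- !is.finite(r) | s1 <= 0 | r >= n | ca < -1 | ca > 1
  ca[bad] <- NA_real_
  b1 <- acos(ca) / (params$nominal_fa_deg * pi / 180)
  b1[bad] <- NaN
  ParameterMap(array(b1, dim(s1)), "B1", subjectId, voxelSize)
}

#' Fit the static field offset B0 from a two-echo phase difference
#'
#' The phase difference is wrapped to (-pi, pi]; B0 in Hz is
#' delta_phi / (2 pi delta_TE).
#'
#' @param phase_te1,phase_te2 3D phase volumes in radians.
#' @param params an [mtParams()] descriptor supplying `te_pair_ms`.
#' @inheritParams fitR2Star
#' @return a B0 [ParameterMap()].
#' @export
fitB0FromPhase <- function(phase_te1, phase_te2, params = mtParams(),
                           subjectId = "unknown", voxelSize = 2) {
  stopIfGridMismatch(phase_te1, phase_te2, "phase volumes")
  dte <- diff(params$te_pair_ms) / 1000
  if (abs(dte) < 1e-12) stop("delta TE must be non-zero")
  dphi <- wrapPhase(phase_te2 - phase_te1)
  ParameterMap(array(dphi / (2 * pi * dte), dim(phase_te1)), "B0",
               subjectId, voxelSize)
}

#' Fit R1 from a two-point variable flip angle SPGR pair
#'
#' Linearizes the SPGR equation: with y = S/sin(a) and x = S/tan(a) the two
#' B1-corrected flip angles give E1 as the slope; R1 = -log(E1)/TR. An
#' optional multiplicative spoiling correction is applied to the recovered
#' T1 (identity by default).
#'
#' @param s_low,s_high 3D volumes at the low and high flip angle.
#' @param params a [vfaParams()] descriptor.
#' @param b1 optional B1 [ParameterMap-class] (or array) scaling the angles.
#' @param spoilingCorrection function(t1_s) -> corrected t1_s; identity by
#'   default (the published corrections are protocol-specific polynomials).
#' @inheritParams fitR2Star
#' @return an R1 [ParameterMap()].
#' @export
fitR1Vfa <- function(s_low, s_high, params = vfaParams(), b1 = NULL,
                     spoilingCorrection = identity,
                     subjectId = "unknown", voxelSize = 2) {
  stopIfGridMismatch(s_low, s_high, "VFA volumes")
  b1v <- if (is.null(b1)) 1 else if (is(b1, "ParameterMap")) b1@data else b1
  a1 <- params$flip_angles_deg[1] * pi / 180 * b1v
  a2 <- params$flip_angles_deg[2] * pi / 180 * b1v
  y1 <- s_low / sin(a1);  x1 <- s_low / tan(a1)
  y2 <- s_high / sin(a2); x2 <- s_high / tan(a2)
  e1 <- (y2 - y1) / (x2 - x1)
  bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  e1[bad] <- NA_real_
  t1 <- -(params$tr_ms / 1000) / log(e1)
  t1 <- spoilingCorrection(t1)
  r1 <- 1 / t1
  r1[bad] <- NaN
  ParameterMap(array(r1, dim(s_low)), "R1", subjectId, voxelSize)
}

## --------------------------------------------------------------------------
## pSSFP R2: ratio(T2, B1) table from the Bloch steady state, inverted by
## monotone interpolation with the assumed global T1. Cached per parameter
## signature so repeated fits reuse the table.
## --------------------------------------------------------------------------

.pssfpCache <- new.env(parent = emptyenv())

pssfpRatioTable <- function(params = pssfpParams(),
                            b1_grid = seq(0.8, 1.2, by = 0.05),
                            t2_grid = exp(seq(log(0.004), log(0.6),
                                              length.out = 60))) {
  key <- paste(c(unlist(params[c("tr_ms", "fa_deg", "assumed_t1_s")],
                        use.names = FALSE),
                 params$spoil_increments_deg, range(b1_grid), length(b1_grid),
                 range(t2_grid), length(t2_grid)), collapse = "|")
  if (!is.null(.pssfpCache[[key]])) return(.pssfpCache[[key]])
  ratio <- matrix(NA_real_, length(t2_grid), length(b1_grid))
  for (j in seq_along(b1_grid)) {
    fa <- params$fa_deg * b1_grid[j]
    s1 <- pssfpSignal(t2_grid, params$assumed_t1_s, fa, params$tr_ms,
                      params$spoil_increments_deg[1])
    s2 <- pssfpSignal(t2_grid, params$assumed_t1_s, fa, params$tr_ms,
                      params$spoil_increments_deg[2])
    r <- s1 / s2
    ratio[, j] <- cummax(r)   # enforce monotonicity against simulation noise
  }
  out <- list(t2 = t2_grid, b1 = b1_grid, ratio = ratio)
  .pssfpCache[[key]] <- out
  out
}

#' Fit R2 from a partially spoiled SSFP pair
#'
#' The ratio of the two spoil-increment acquisitions is inverted for T2
#' through the simulated steady-state relation at the assumed global T1
#' (default 1.25 s), with B1-corrected flip angle. T2 is capped at
#' `params$t2_cap_ms` before conversion to R2 = 1/T2. Ratios outside the
#' admissible range of the relation give NaN.
#'
#' @param s_inc1,s_inc2 volumes acquired with the small (nearly coherent)
#'   and large (strongly spoiled) RF-spoiling increments.
#' @param params a [pssfpParams()] descriptor.
#' @param b1 optional B1 map (ParameterMap or array).
#' @inheritParams fitR2Star
#' @return an R2 [ParameterMap()].
#' @export
fitR2Pssfp <- function(s_inc1, s_inc2, params = pssfpParams(), b1 = NULL,
                       subjectId = "unknown", voxelSize = 2) {
  stopIfGridMismatch(s_inc1, s_inc2, "pSSFP volumes")
  tab <- pssfpRatioTable(params)
  b1v <- if (is.null(b1)) 1 else if (is(b1, "ParameterMap")) b1@data else b1
  b1v <- rep_len(as.vector(b1v), length(s_inc1))
  b1v <- pmin(pmax(b1v, min(tab$b1)), max(tab$b1))
  robs <- as.vector(s_inc1 / s_inc2)
  ok <- is.finite(robs) & is.finite(b1v) & as.vector(s_inc2) > 0
  logt2 <- log(tab$t2)
  ## invert at each tabulated B1, then blend linearly in B1
  nb <- length(tab$b1)
  invAt <- function(j, r) {
    stats::approx(tab$ratio[, j], logt2, xout = r, rule = 1)$y
  }
  t2 <- rep(NaN, length(robs))
  jlo <- pmin(pmax(findInterval(b1v, tab$b1), 1L), nb - 1L)
  w <- (b1v - tab$b1[jlo]) / (tab$b1[jlo + 1L] - tab$b1[jlo])
  for (j in seq_len(nb - 1L)) {
    sel <- which(ok & jlo == j)
    if (!length(sel)) next
    lo <- invAt(j, robs[sel]); hi <- invAt(j + 1L, robs[sel])
    t2[sel] <- exp((1 - w[sel]) * lo + w[sel] * hi)
  }
  t2[is.na(t2)] <- NaN                 # invalid-voxel convention
  t2 <- pmin(t2, params$t2_cap_ms / 1000)
  r2 <- 1 / t2
  ParameterMap(array(r2, dim(s_inc1)), "R2", subjectId, voxelSize)
}

#' Derive R2' = R2* - R2
#'
#' Voxelwise difference of the effective and irreversible transverse rates,
#' isolating static-field-inhomogeneity losses. Negative values (possible
#' under noise) are retained; their count is attached as attribute
#' `"nNegative"` for QC.
#'
#' @param r2star,r2 [ParameterMap-class] objects on the same grid and subject.
#' @return an R2prime [ParameterMap()].
#' @export
deriveR2Prime <- function(r2star, r2) {
  stopifnot(is(r2star, "ParameterMap"), is(r2, "ParameterMap"))
  stopIfGridMismatch(r2star@data, r2@data, "R2* and R2")
  if (!identical(r2star@subjectId, r2@subjectId))
    stop("R2* and R2 belong to different subjects")
  d <- r2star@data - r2@data
  out <- ParameterMap(d, "R2prime", r2star@subjectId, r2star@voxelSize)
  attr(out@data, "nNegative") <- sum(d < 0, na.rm = TRUE)
  out
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable Gaussian smoothing with sigma = fwhm / 2.3548 per axis (in mm,
#' converted through the voxel size). Non-finite voxels are excluded by
#' normalized convolution, so NaNs neither spread nor bias their neighbours.
#' `fwhm_mm = 0` is the identity.
#'
#' @param x a [ParameterMap-class] or 3D array.
#' @param fwhm_mm full width at half maximum of the kernel in mm.
#' @param voxelSize voxel size in mm (ignored for ParameterMap input).
#' @return object of the same type as `x`.
#' @export
smoothVolume <- function(x, fwhm_mm = 5, voxelSize = 2) {
  ismap <- is(x, "ParameterMap")
  vol <- if (ismap) x@data else x
  vs <- if (ismap) x@voxelSize else rep_len(voxelSize, 3L)
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(x)
  sigma_vox <- (fwhm_mm / 2.3548) / vs
  fin <- is.finite(vol)
  num <- vol; num[!fin] <- 0
  den <- array(as.numeric(fin), dim(vol))
  for (ax in 1:3) {
    num <- convolveAxis(num, sigma_vox[ax], ax)
    den <- convolveAxis(den, sigma_vox[ax], ax)
  }
  out <- num / den
  out[!fin] <- vol[!fin]
  out[den < 1e-12] <- NaN
  if (ismap) ParameterMap(out, x@paramId, x@subjectId, vs) else out
}

## 1D smoothing along axis `ax` with the discrete Gaussian kernel
## k_j = exp(-t) I_j(t), t = sigma^2 (modified Bessel of the first kind):
## the discrete analogue of Gaussian convolution. It is non-negative, sums
## to 1, and is exactly closed under convolution (t1 + t2 = t), so repeated
## smoothing obeys the Gaussian semigroup. Zero-padded at the volume faces.
convolveAxis <- function(vol, sigma, ax) {
  if (sigma <= 0) return(vol)
  t <- sigma^2
  r <- max(2L, ceiling(4 * sigma + 4))
  k <- besselI(t, 0:r, expon.scaled = TRUE)
  k <- c(rev(k[-1]), k)
  k <- k / sum(k)
  d <- dim(vol)
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vol, perm)
  n <- d[ax]
  m <- matrix(v, nrow = n)
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n); j <- i + o
    sel <- j >= 1 & j <= n
    K[cbind(i[sel], j[sel])] <- k[o + r + 1]
  }
  res <- K %*% m
  aperm(array(res, d[perm]), order(perm))
}
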