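#' Fit the macromolecular proton fraction by the single-point method
#'
#' Solves the pulsed two-pool magnetization-transfer steady state
#' ([mtSignalRatio()]) for the bound-pool fraction f from a single
#' MT-weighted / reference signal ratio, with the remaining model parameters
#' constrained (see [twoPoolConstraints()]): R1f = R1b = measured R1,
#' T2b fixed, T2f tied to T1, and the exchange rate k(1-f)/f fixed. The
#' offset is shifted by the B0 map and the saturation and readout angles are
#' scaled by the B1 map. Bounded bisection on f in [0, 0.35] to a tolerance
#' of 1e-6; voxels whose ratio lies outside the model's range (no sign
#' change on the bracket) become NaN, as do non-positive ratios.
#'
#' @param mt_img,ref_img 3D volumes: MT-weighted and reference signal.
#' @param r1 R1 [ParameterMap-class] (or array, s^-1).
#' @param b0 optional B0 map (Hz); zero if NULL.
#' @param b1 optional B1 map; one if NULL.
#' @param params an [mtParams()] descriptor.
#' @param constraints a [twoPoolConstraints()] set.
#' @param f_max upper bracket for the bound-pool fraction.
#' @inheritParams fitR2Star
#' @return an MPF [ParameterMap()] in percent (100 f).
#' @export
fitMpfSinglePoint <- function(mt_img, ref_img, r1, b0 = NULL, b1 = NULL,
                              params = mtParams(),
                              constraints = twoPoolConstraints(),
                              f_max = 0.35,
                              subjectId = "unknown", voxelSize = 2) {
  stopIfGridMismatch(mt_img, ref_img, "MT and reference volumes")
  getArr <- function(x, default) {
    if (is.null(x)) default
    else if (is(x, "ParameterMap")) as.vector(x@data)
    else as.vector(x)
  }
  n <- length(mt_img)
  r1v <- rep_len(getArr(r1, NA_real_), n)
  b0v <- rep_len(getArr(b0, 0), n)
  b1v <- rep_len(getArr(b1, 1), n)
  robs <- as.vector(mt_img) / as.vector(ref_img)
  ok <- is.finite(robs) & robs > 0 & robs <= 1.2 &
    is.finite(r1v) & r1v > 0 & is.finite(b0v) & is.finite(b1v) & b1v > 0
  idx <- which(ok)
  fout <- rep(NaN, n)
  if (length(idx)) {
    r1s <- r1v[idx]; b0s <- b0v[idx]; b1s <- b1v[idx]; rs <- robs[idx]
    resid <- function(f) {
      mtSignalRatio(f, r1s, b0s, b1s, params, constraints) - rs
    }
    lo <- rep(0, length(idx)); hi <- rep(f_max, length(idx))
    rlo <- resid(lo); rhi <- resid(hi)
    bracket <- is.finite(rlo) & is.finite(rhi) & rlo * rhi <= 0
    ## bisection, vectorized over voxels; 40 halvings of 0.35 < 1e-6 on f
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      rmid <- resid(mid)
      up <- rlo * rmid <= 0
      hi[up] <- mid[up]; rhi[up] <- rmid[up]
      lo[!up] <- mid[!up]; rlo[!up] <- rmid[!up]
    }
    f <- (lo + hi) / 2
    f[!bracket] <- NaN
    fout[idx] <- f
  }
  ParameterMap(array(100 * fout, dim(mt_img)), "MPF", subjectId, voxelSize)
}
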