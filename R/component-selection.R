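#' Between-parameter over between-subject loading-SD ratio
#'
#' Reshapes one component's mixing column by its (subject, parameter) row
#' index and computes the SD over parameters of the parameter-wise mean
#' loadings divided by the SD over subjects of the subject-wise mean
#' loadings. Components shared across subjects but differentiating the
#' parameters score high; subject-driven components score low. A small
#' epsilon guards the denominator.
#'
#' @param loadings numeric vector, one mixing weight per group-matrix row.
#' @param rowIndex data.frame with `subject` and `param` for each row.
#' @param eps denominator guard.
#' @return the ratio (NA if fewer than 2 subjects or 2 parameters).
#' @export
paramSubjectRatio <- function(loadings, rowIndex, eps = 1e-12) {
  pm <- tapply(loadings, rowIndex$param, mean)
  sm <- tapply(loadings, rowIndex$subject, mean)
  if (length(pm) < 2L || length(sm) < 2L) return(NA_real_)
  stats::sd(pm) / max(stats::sd(sm), eps)
}

#' WM spatial overlap of a component's positive suprathreshold voxels
#'
#' @param cs a [ComponentSet-class].
#' @param wmProb 3D WM probability map.
#' @param zThresh z threshold defining the positive distribution.
#' @param wmPMin WM probability above which a voxel counts as WM.
#' @return numeric vector: per component, the fraction of z >= zThresh
#'   voxels with WM probability > wmPMin (0 when no voxel passes).
#' @export
componentWmOverlap <- function(cs, wmProb, zThresh = 2, wmPMin = 0.5) {
  wmv <- wmProb[cs@voxelIndex]
  apply(cs@sources, 1, function(z) {
    sel <- z >= zThresh
    if (!any(sel)) return(0)
    mean(wmv[sel] > wmPMin)
  })
}

#' Select WM-subtype components
#'
#' Keeps components whose positive suprathreshold distribution overlaps WM
#' (`wmOverlap >= overlapMin`) and whose between-parameter over
#' between-subject loading-SD ratio is at least `ratioMin` (default 1.5).
#' Zero selected components is a legal outcome.
#'
#' @param cs a [ComponentSet-class].
#' @param wmProb 3D WM probability map.
#' @param zThresh z threshold for the overlap criterion.
#' @param overlapMin minimum WM overlap fraction.
#' @param ratioMin minimum loading-SD ratio.
#' @param wmPMin WM probability cut for the overlap criterion.
#' @return a [ComponentSet-class] containing only the selected components,
#'   with `wmOverlap` filled in its stats (the full annotated stats table is
#'   attached as attribute `"allStats"`).
#' @export
selectWmComponents <- function(cs, wmProb, zThresh = 2, overlapMin = 0.5,
                               ratioMin = 1.5, wmPMin = 0.5) {
  stopifnot(is(cs, "ComponentSet"))
  ov <- componentWmOverlap(cs, wmProb, zThresh, wmPMin)
  cs@stats$wmOverlap <- ov
  keep <- which(ov >= overlapMin & !is.na(cs@stats$ratio) &
                  cs@stats$ratio >= ratioMin)
  out <- subsetComponents(cs, keep)
  attr(out, "allStats") <- cs@stats
  out
}
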