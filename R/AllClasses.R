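#' @import methods
NULL

## Canonical parameter identifiers and their units.
.PARAM_UNITS <- c(
  R1 = "s^-1", R2 = "s^-1", R2star = "s^-1", R2prime = "s^-1",
  AD = "um^2/s", RD = "um^2/s", ADC = "um^2/s", FA = "",
  chi_m = "ppb", MPF = "percent", B1 = "", B0 = "Hz",
  pWM = "", pGM = "", S0 = "a.u."
)

#' Units of a quantitative parameter
#'
#' @param paramId character parameter identifier (e.g. `"R1"`, `"MPF"`).
#' @return character unit string (`"s^-1"`, `"um^2/s"`, ...).
#' @export
paramUnits <- function(paramId) {
  u <- .PARAM_UNITS[paramId]
  if (anyNA(u)) stop("unknown parameter id: ",
                     paste(paramId[is.na(u)], collapse = ", "))
  unname(u)
}

#' ParameterMap: one quantitative 3D volume
#'
#' A single quantitative parameter map on a regular voxel grid, tagged with
#' the parameter identity, its units and the subject it belongs to. Invalid
#' voxels are stored as `NaN` and excluded from all downstream computation.
#'
#' @slot data 3D numeric array of parameter values.
#' @slot paramId parameter identifier (one of `names(wmsubtypes:::.PARAM_UNITS)`).
#' @slot units unit string (filled from [paramUnits()] by the constructor).
#' @slot subjectId subject identifier.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @export
setClass("ParameterMap",
  representation(data = "array", paramId = "character", units = "character",
                 subjectId = "character", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!object@paramId %in% names(.PARAM_UNITS))
      msg <- c(msg, paste0("unknown paramId '", object@paramId, "'"))
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
    v <- object@data[is.finite(object@data)]
    if (length(v)) {
      if (object@paramId == "FA" && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
        msg <- c(msg, "FA values must lie in [0, 1]")
      if (object@paramId %in% c("pWM", "pGM") &&
          (min(v) < -1e-9 || max(v) > 1 + 1e-9))
        msg <- c(msg, "probability maps must lie in [0, 1]")
      if (object@paramId == "MPF" && (min(v) < -1e-9 || max(v) > 35 + 1e-9))
        msg <- c(msg, "MPF must lie in [0, 35] percent")
      if (object@paramId %in% c("R1", "R2", "R2star") && min(v) < -1e-9)
        msg <- c(msg, "relaxation rates must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ParameterMap
#'
#' @param data 3D numeric array.
#' @param paramId parameter identifier, see [paramUnits()].
#' @param subjectId subject identifier.
#' @param voxelSize voxel size in mm (length 1 or 3).
#' @return a [ParameterMap-class] object.
#' @export
ParameterMap <- function(data, paramId, subjectId = "unknown", voxelSize = 2) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("ParameterMap", data = data, paramId = paramId,
      units = paramUnits(paramId), subjectId = as.character(subjectId),
      voxelSize = as.numeric(voxelSize))
}

#' @describeIn ParameterMap-class voxel data array
#' @param object,x a `ParameterMap`.
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))
#' @export
setMethod("mapData", "ParameterMap", function(x) x@data)

#' @export
setGeneric("paramId", function(x) standardGeneric("paramId"))
#' @export
setMethod("paramId", "ParameterMap", function(x) x@paramId)

#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "ParameterMap", function(x) x@subjectId)

setMethod("show", "ParameterMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ParameterMap %s [%s] subject %s, %dx%dx%d @ %g mm, %d finite voxels\n",
              object@paramId, object@units, object@subjectId,
              d[1], d[2], d[3], object@voxelSize[1],
              sum(is.finite(object@data))))
})

#' SubjectRecord: one subject's map set
#'
#' Holds a subject's (possibly incomplete) set of quantitative maps together
#' with the tissue probability maps used for masking.
#'
#' @slot subjectId subject identifier.
#' @slot maps named list of [ParameterMap-class] objects.
#' @slot pWM,pGM 3D arrays of WM / GM probability in `[0, 1]`.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", maps = "list",
                 pWM = "array", pGM = "array"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@pWM)
    for (m in object@maps) {
      if (!is(m, "ParameterMap")) { msg <- c(msg, "maps must be ParameterMap"); break }
      if (!identical(dim(m@data), d))
        msg <- c(msg, paste0("grid mismatch for map ", m@paramId))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @export
SubjectRecord <- function(subjectId, maps, pWM, pGM) {
  names(maps) <- vapply(maps, function(m) m@paramId, character(1))
  new("SubjectRecord", subjectId = as.character(subjectId), maps = maps,
      pWM = pWM, pGM = pGM)
}

#' @export
setGeneric("subjectMaps", function(x) standardGeneric("subjectMaps"))
#' @export
setMethod("subjectMaps", "SubjectRecord", function(x) x@maps)
#' @export
setMethod("subjectId", "SubjectRecord", function(x) x@subjectId)

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: %d maps (%s)\n", object@subjectId,
              length(object@maps), paste(names(object@maps), collapse = ", ")))
})

#' PhantomCohort: a synthetic multi-subject map set with ground truth
#'
#' @slot records list of [SubjectRecord-class].
#' @slot covariates data.frame with columns `subject`, `age`, `gender`.
#' @slot groundTruth list: component weight fields, true (pre-noise) in-core
#'   fingerprints, planted covariate effects, tract label volumes.
#' @slot spec the generating [phantomSpec()] list.
#' @export
setClass("PhantomCohort",
  representation(records = "list", covariates = "data.frame",
                 groundTruth = "list", spec = "list"))

setMethod("show", "PhantomCohort", function(object) {
  nmap <- sum(vapply(object@records, function(r) length(r@maps), integer(1)))
  cat(sprintf("PhantomCohort: %d subjects, %d maps, grid %s, %d planted components\n",
              length(object@records), nmap,
              paste(object@spec$grid_shape, collapse = "x"),
              length(object@groundTruth$weights)))
})

#' @export
setGeneric("cohortRecords", function(x) standardGeneric("cohortRecords"))
#' @export
setMethod("cohortRecords", "PhantomCohort", function(x) x@records)
#' @export
setGeneric("cohortCovariates", function(x) standardGeneric("cohortCovariates"))
#' @export
setMethod("cohortCovariates", "PhantomCohort", function(x) x@covariates)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "PhantomCohort", function(x) x@groundTruth)

#' GroupMatrix: stacked (subject, parameter) maps by voxels
#'
#' The unfolded 2D matrix feeding spatial ICA: one row per available
#' normalized map, one column per in-mask voxel.
#'
#' @slot data numeric matrix, rows = maps, columns = voxels.
#' @slot rowIndex data.frame with columns `subject`, `param` (one row per
#'   matrix row).
#' @slot voxelIndex integer vector: column -> linear voxel index in the grid.
#' @slot gridDim integer length-3 grid dimensions.
#' @slot mask logical 3D analysis mask (TRUE exactly at `voxelIndex`).
#' @export
setClass("GroupMatrix",
  representation(data = "matrix", rowIndex = "data.frame",
                 voxelIndex = "integer", gridDim = "integer", mask = "array"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@data) != nrow(object@rowIndex))
      msg <- c(msg, "rowIndex must have one row per matrix row")
    if (ncol(object@data) != length(object@voxelIndex))
      msg <- c(msg, "voxelIndex must have one entry per matrix column")
    if (anyNA(object@data)) msg <- c(msg, "group matrix must not contain NA")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "GroupMatrix", function(object) {
  cat(sprintf("GroupMatrix: %d maps x %d voxels (%d subjects, %d parameters)\n",
              nrow(object@data), ncol(object@data),
              length(unique(object@rowIndex$subject)),
              length(unique(object@rowIndex$param))))
})

#' @export
setGeneric("matrixData", function(x) standardGeneric("matrixData"))
#' @export
setMethod("matrixData", "GroupMatrix", function(x) x@data)
#' @export
setGeneric("rowIndex", function(x) standardGeneric("rowIndex"))
#' @export
setMethod("rowIndex", "GroupMatrix", function(x) x@rowIndex)

#' ComponentSet: spatial ICA result
#'
#' @slot sources numeric matrix, components x voxels; each row z-scored over
#'   the analysis mask and sign-fixed to non-negative skewness.
#' @slot loadings numeric matrix, matrix rows x components (mixing weights).
#' @slot rowIndex as in [GroupMatrix-class].
#' @slot stats data.frame per component: `ratio` (between-parameter over
#'   between-subject SD of loadings), `wmOverlap`, `varExplained`, `skewness`.
#' @slot voxelIndex,gridDim,mask grid bookkeeping, as in [GroupMatrix-class].
#' @slot modelOrder the N of this decomposition.
#' @slot seed RNG seed used.
#' @export
setClass("ComponentSet",
  representation(sources = "matrix", loadings = "matrix",
                 rowIndex = "data.frame", stats = "data.frame",
                 voxelIndex = "integer", gridDim = "integer", mask = "array",
                 modelOrder = "integer", seed = "integer"))

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: N = %d (model order %d), %d voxels; varExplained %s\n",
              nrow(object@sources), object@modelOrder, ncol(object@sources),
              paste(sprintf("%.3f", object@stats$varExplained), collapse = " ")))
})

#' @export
setGeneric("componentStats", function(x) standardGeneric("componentStats"))
#' @export
setMethod("componentStats", "ComponentSet", function(x) x@stats)
#' @export
setGeneric("componentSources", function(x) standardGeneric("componentSources"))
#' @export
setMethod("componentSources", "ComponentSet", function(x) x@sources)
#' @export
setGeneric("componentLoadings", function(x) standardGeneric("componentLoadings"))
#' @export
setMethod("componentLoadings", "ComponentSet", function(x) x@loadings)

#' Fold one component's z-scores back into a 3D map
#'
#' @param x a `ComponentSet`.
#' @param i component index.
#' @return 3D array, `NA` outside the analysis mask.
#' @export
componentZMap <- function(x, i) {
  stopifnot(is(x, "ComponentSet"))
  vol <- array(NA_real_, x@gridDim)
  vol[x@voxelIndex] <- x@sources[i, ]
  vol
}

#' SubtypeAtlas: averaged, matched subtype maps with reproducibility stats
#'
#' @slot zMaps named list of 3D z-score arrays, one per subtype.
#' @slot displayMaps list of logical arrays: z >= display threshold with the
#'   cluster-extent filter applied (display only).
#' @slot kappa data.frame: subtype, threshold, kappa, nRuns.
#' @slot dice pairwise Dice overlap of subtype masks at the display threshold.
#' @slot thresholds list: `zDisplay`, `zExtract`, `clusterK`.
#' @slot memberZ list (per subtype) of matrices run x voxel used for kappa.
#' @slot voxelIndex,gridDim,mask grid bookkeeping.
#' @export
setClass("SubtypeAtlas",
  representation(zMaps = "list", displayMaps = "list", kappa = "data.frame",
                 dice = "matrix", thresholds = "list", memberZ = "list",
                 voxelIndex = "integer", gridDim = "integer", mask = "array"))

setMethod("show", "SubtypeAtlas", function(object) {
  cat(sprintf("SubtypeAtlas: %d subtypes (%s); thresholds z>=%g display / z>=%g extract, k>=%d\n",
              length(object@zMaps), paste(names(object@zMaps), collapse = ", "),
              object@thresholds$zDisplay, object@thresholds$zExtract,
              object@thresholds$clusterK))
  if (nrow(object@kappa)) {
    cat("Fleiss kappa:\n"); print(object@kappa, row.names = FALSE)
  }
})

#' @export
setGeneric("atlasZMaps", function(x) standardGeneric("atlasZMaps"))
#' @export
setMethod("atlasZMaps", "SubtypeAtlas", function(x) x@zMaps)
#' @export
setGeneric("kappaTable", function(x) standardGeneric("kappaTable"))
#' @export
setMethod("kappaTable", "SubtypeAtlas", function(x) x@kappa)
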