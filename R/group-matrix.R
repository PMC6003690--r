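#' Group-level intensity normalization of parameter maps
#'
#' For each parameter, one mean and SD are computed over the in-mask voxels
#' of all subjects' maps jointly, every map is transformed to
#' (x - mean)/SD, and values are clamped to [-clamp, clamp] (default 4 SD)
#' to limit outlier leverage. Group-level (rather than per-subject)
#' scaling preserves between-subject variance in the decomposition.
#'
#' @param records list of [SubjectRecord-class] (or a [PhantomCohort-class]).
#' @param mask logical 3D array of in-brain analysis voxels.
#' @param params parameters to normalize; default all present.
#' @param clamp clamp bound in group SD units.
#' @return list with `records` (maps replaced by scaled maps) and
#'   `stats` (data.frame param/mean/sd/n).
#' @export
normalizeGroupIntensity <- function(records, mask, params = NULL, clamp = 4) {
  if (is(records, "PhantomCohort")) records <- records@records
  allp <- unique(unlist(lapply(records, function(r) names(r@maps))))
  params <- params %||% allp
  stats <- data.frame(param = params, mean = NA_real_, sd = NA_real_,
                      n = NA_integer_)
  midx <- which(mask)
  for (k in seq_along(params)) {
    p <- params[k]
    have <- which(vapply(records, function(r) p %in% names(r@maps), logical(1)))
    if (length(have) < 2L)
      stop("parameter ", p, " present for fewer than 2 subjects")
    vals <- unlist(lapply(records[have],
                          function(r) r@maps[[p]]@data[midx]))
    vals <- vals[is.finite(vals)]
    mu <- mean(vals); sd <- stats::sd(vals)
    if (!is.finite(sd) || sd == 0) stop("zero group SD for parameter ", p)
    stats$mean[k] <- mu; stats$sd[k] <- sd; stats$n[k] <- length(have)
    for (i in have) {
      m <- records[[i]]@maps[[p]]
      z <- (m@data - mu) / sd
      z <- pmin(pmax(z, -clamp), clamp)
      ## normalized maps are unitless; store as plain slot update
      m@data <- z
      m@units <- "sd"
      records[[i]]@maps[[p]] <- m
    }
  }
  list(records = records, stats = stats)
}

#' Prepare subject maps for decomposition
#'
#' Restricts each map to the analysis mask (exterior voxels become NaN so
#' smoothing cannot bleed background values into the brain edge), smooths
#' with an isotropic Gaussian kernel, and applies group-level intensity
#' normalization.
#'
#' @param records list of [SubjectRecord-class] or a [PhantomCohort-class].
#' @param mask logical 3D in-brain analysis mask.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 = no smoothing).
#' @param clamp normalization clamp in group SD units.
#' @return as [normalizeGroupIntensity()].
#' @export
prepareMapsForDecomposition <- function(records, mask, fwhm_mm = 5,
                                        clamp = 4) {
  if (is(records, "PhantomCohort")) records <- records@records
  for (i in seq_along(records)) for (p in names(records[[i]]@maps)) {
    m <- records[[i]]@maps[[p]]
    m@data[!mask] <- NaN
    if (fwhm_mm > 0) m <- smoothVolume(m, fwhm_mm)
    records[[i]]@maps[[p]] <- m
  }
  normalizeGroupIntensity(records, mask, clamp = clamp)
}

#' Build the group matrix from normalized maps
#'
#' Unfolds all available (subject, parameter) maps into a 2D matrix with
#' one row per map and one column per analysis voxel. Columns are restricted
#' to in-mask voxels at which every row is finite, so the matrix carries no
#' NaN.
#'
#' @param records list of [SubjectRecord-class] with normalized maps.
#' @param mask logical 3D in-brain analysis mask.
#' @return a [GroupMatrix-class].
#' @export
buildGroupMatrix <- function(records, mask) {
  if (is(records, "PhantomCohort")) records <- records@records
  d <- dim(mask)
  rows <- list(); subj <- character(); par <- character()
  for (r in records) for (p in names(r@maps)) {
    rows[[length(rows) + 1L]] <- r@maps[[p]]@data
    subj <- c(subj, r@subjectId); par <- c(par, p)
  }
  if (!length(rows)) stop("no maps available")
  vox <- which(mask)
  if (!length(vox)) stop("empty analysis mask")
  M <- vapply(rows, function(v) v[vox], numeric(length(vox)))
  keep <- rowSums(!is.finite(M)) == 0L
  if (!any(keep)) stop("no voxel is finite across all rows")
  vox <- vox[keep]
  M <- t(M[keep, , drop = FALSE])
  amask <- array(FALSE, d); amask[vox] <- TRUE
  new("GroupMatrix", data = M,
      rowIndex = data.frame(subject = subj, param = par,
                            stringsAsFactors = FALSE),
      voxelIndex = as.integer(vox), gridDim = as.integer(d), mask = amask)
}

#' Fold a group-matrix row back into a 3D map
#'
#' @param gm a [GroupMatrix-class].
#' @param i row number.
#' @return 3D array with `NA` outside the analysis mask.
#' @export
foldRow <- function(gm, i) {
  vol <- array(NA_real_, gm@gridDim)
  vol[gm@voxelIndex] <- gm@data[i, ]
  vol
}
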