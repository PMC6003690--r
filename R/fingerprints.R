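#' Extract per-subject per-subtype parameter fingerprints
#'
#' For every subject and subtype, averages each (unsmoothed) parameter map
#' over the subtype ROI — the averaged component map thresholded at
#' `z_min` — restricted to voxels the subject's WM probability map marks as
#' WM (`> wm_p_min`). Cells with a missing map or fewer than `min_voxels`
#' eligible voxels are NaN. A `pWM` column records the mean WM probability
#' over the ROI. With `include_gm`, an extra "GM" row per subject uses the
#' GM probability gate over the whole brain as a comparison tissue.
#'
#' @param atlas a [SubtypeAtlas-class], or a named list of logical 3D ROI
#'   masks (e.g. ground-truth component cores).
#' @param records list of [SubjectRecord-class] or a [PhantomCohort-class]
#'   (whose covariates are then joined automatically).
#' @param covariates optional data.frame with `subject`, `age`, `gender`.
#' @param z_min extraction z threshold.
#' @param wm_p_min WM probability gate.
#' @param include_gm add a GM comparison row per subject.
#' @param min_voxels minimum eligible voxels per cell.
#' @return data.frame: `subject`, `subtype`, one column per parameter,
#'   `pWM`, and covariates when available.
#' @export
extractFingerprintTable <- function(atlas, records, covariates = NULL,
                                    z_min = 3.2, wm_p_min = 0.8,
                                    include_gm = FALSE, min_voxels = 10L) {
  if (is(records, "PhantomCohort")) {
    covariates <- covariates %||% records@covariates
    records <- records@records
  }
  rois <- if (is(atlas, "SubtypeAtlas")) {
    lapply(atlas@zMaps, function(z) !is.na(z) & z >= z_min)
  } else {
    stopifnot(is.list(atlas))
    atlas
  }
  params <- unique(unlist(lapply(records, function(r) names(r@maps))))
  rows <- list()
  anyEligible <- FALSE
  for (r in records) {
    gate <- r@pWM > wm_p_min
    for (sn in names(rois)) {
      vox <- which(rois[[sn]] & gate)
      if (length(vox) >= min_voxels) anyEligible <- TRUE
      cell <- vapply(params, function(p) {
        if (!p %in% names(r@maps)) return(NaN)
        v <- r@maps[[p]]@data[vox]
        v <- v[is.finite(v)]
        if (length(v) < min_voxels) NaN else mean(v)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = r@subjectId, subtype = sn, t(cell),
        pWM = if (length(vox) >= min_voxels) mean(r@pWM[vox]) else NaN,
        stringsAsFactors = FALSE)
    }
    if (include_gm) {
      vox <- which(r@pGM > wm_p_min)
      cell <- vapply(params, function(p) {
        if (!p %in% names(r@maps)) return(NaN)
        v <- r@maps[[p]]@data[vox]
        v <- v[is.finite(v)]
        if (length(v) < min_voxels) NaN else mean(v)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = r@subjectId, subtype = "GM", t(cell),
        pWM = if (length(vox)) mean(r@pWM[vox]) else NaN,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!anyEligible) {
    if (all(vapply(rois, sum, numeric(1)) == 0))
      stop("empty ROI after gating for all subjects; atlas rejected")
    warning("no subject has >= ", min_voxels,
            " eligible voxels in any ROI; table is all-NaN")
  }
  if (!is.null(covariates)) {
    tab <- merge(tab, covariates, by = "subject", sort = FALSE)
  }
  tab[order(tab$subject, tab$subtype), , drop = FALSE]
}

.subtypePairs <- function(subtypes) {
  if (length(subtypes) < 2L) return(NULL)
  cmb <- utils::combn(subtypes, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Paired t-tests between subtype fingerprints
#'
#' Paired t-test per parameter per subtype pair on subject-wise ROI means,
#' with casewise deletion. Significance is flagged at the Bonferroni
#' threshold `alpha / m` (m = number of tests) unless an explicit corrected
#' cutoff is supplied.
#'
#' @param tab a fingerprint table from [extractFingerprintTable()].
#' @param params parameter columns to test (default: all present).
#' @param alpha family-wise error rate.
#' @param correctedAlpha explicit per-test cutoff overriding `alpha / m`.
#' @return data.frame: param, pair, n, t, df, p, significant.
#' @export
pairedSubtypeTests <- function(tab, params = NULL, alpha = 0.05,
                               correctedAlpha = NULL) {
  params <- params %||% setdiff(colnames(tab),
                                c("subject", "subtype", "pWM", "age", "gender"))
  subtypes <- setdiff(unique(tab$subtype), "GM")
  pairs <- .subtypePairs(subtypes)
  res <- list()
  for (pr in pairs) for (p in params) {
    x <- tab[tab$subtype == pr[1], c("subject", p)]
    y <- tab[tab$subtype == pr[2], c("subject", p)]
    m <- merge(x, y, by = "subject")
    d <- m[[2]] - m[[3]]
    d <- d[is.finite(d)]
    n <- length(d)
    nm <- paste(pr, collapse = " vs ")
    if (n < 3L) {
      warning("fewer than 3 complete pairs for ", p, " (", nm, ")")
      row <- data.frame(param = p, pair = nm, n = n, t = NA_real_,
                        df = NA_real_, p = NA_real_, significant = NA)
    } else if (stats::sd(d) <= 1e-12 * max(abs(mean(d)), 1)) {
      ## degenerate within-pair variance
      if (mean(d) == 0) row <- data.frame(param = p, pair = nm, n = n, t = 0,
                                          df = n - 1, p = 1, significant = FALSE)
      else row <- data.frame(param = p, pair = nm, n = n, t = Inf * sign(mean(d)),
                             df = n - 1, p = .Machine$double.xmin,
                             significant = TRUE)
    } else {
      tt <- stats::t.test(d)
      row <- data.frame(param = p, pair = nm, n = n,
                        t = unname(tt$statistic), df = unname(tt$parameter),
                        p = tt$p.value, significant = NA)
    }
    res[[length(res) + 1L]] <- row
  }
  out <- do.call(rbind, res)
  mtests <- sum(!is.na(out$p))
  cut <- correctedAlpha %||% (alpha / max(mtests, 1L))
  out$significant <- out$p <= cut
  attr(out, "correctedAlpha") <- cut
  out
}

#' Cohen's d contribution ledger between subtype pairs
#'
#' Effect size d = (m1 - m2) / sqrt((s1^2 + s2^2)/2) per parameter and
#' subtype pair; the cumulative sum of |d| estimates the distance between
#' the subtypes and normalizing by it gives each parameter's relative
#' contribution to the separation.
#'
#' @inheritParams pairedSubtypeTests
#' @return list: `d` (long data.frame param/pair/d/contribution) and
#'   `distance` (per pair).
#' @export
cohensDContributions <- function(tab, params = NULL) {
  params <- params %||% setdiff(colnames(tab),
                                c("subject", "subtype", "pWM", "age", "gender"))
  subtypes <- setdiff(unique(tab$subtype), "GM")
  pairs <- .subtypePairs(subtypes)
  rows <- list(); dist <- list()
  for (pr in pairs) {
    nm <- paste(pr, collapse = " vs ")
    dvec <- vapply(params, function(p) {
      x <- tab[tab$subtype == pr[1], p]; x <- x[is.finite(x)]
      y <- tab[tab$subtype == pr[2], p]; y <- y[is.finite(y)]
      sp <- sqrt((stats::var(x) + stats::var(y)) / 2)
      if (!is.finite(sp) || sp == 0) {
        warning("zero pooled SD for ", p, " (", nm, "); d undefined")
        return(NaN)
      }
      (mean(x) - mean(y)) / sp
    }, numeric(1))
    D <- sum(abs(dvec), na.rm = TRUE)
    contrib <- if (D > 0) abs(dvec) / D else rep(NaN, length(dvec))
    rows[[nm]] <- data.frame(param = params, pair = nm, d = dvec,
                             contribution = contrib, row.names = NULL)
    dist[[nm]] <- D
  }
  list(d = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       distance = unlist(dist))
}

#' Cohen's d with the averaged-variance pooled SD
#'
#' @param m1,m2 group means.
#' @param s1,s2 group SDs.
#' @return (m1 - m2) / sqrt((s1^2 + s2^2)/2).
#' @export
cohensD <- function(m1, s1, m2, s2) (m1 - m2) / sqrt((s1^2 + s2^2) / 2)

#' Within-subtype cross-correlation of parameters
#'
#' Pearson correlations between parameter columns across subjects within
#' each subtype, with two exploratory significance tiers on |r|
#' (defaults 0.38 and 0.48).
#'
#' @inheritParams pairedSubtypeTests
#' @param rTiers the two |r| thresholds.
#' @param minN minimum pairwise-complete observations for a cell.
#' @return named list per subtype: `r`, `n`, and `tier` (0, 1 or 2)
#'   matrices; thresholds attached as attribute `"rTiers"`.
#' @export
crossCorrelationMatrix <- function(tab, params = NULL,
                                   rTiers = c(0.38, 0.48), minN = 4L) {
  params <- params %||% setdiff(colnames(tab),
                                c("subject", "subtype", "pWM", "age", "gender"))
  subtypes <- setdiff(unique(tab$subtype), "GM")
  out <- list()
  for (s in subtypes) {
    X <- as.matrix(tab[tab$subtype == s, params, drop = FALSE])
    k <- length(params)
    r <- matrix(NA_real_, k, k, dimnames = list(params, params))
    n <- matrix(0L, k, k, dimnames = list(params, params))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ok <- is.finite(X[, i]) & is.finite(X[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] >= minN && stats::sd(X[ok, i]) > 0 && stats::sd(X[ok, j]) > 0)
        r[i, j] <- stats::cor(X[ok, i], X[ok, j])
    }
    tier <- (abs(r) >= rTiers[1]) + (abs(r) >= rTiers[2])
    out[[s]] <- list(r = r, n = n, tier = tier)
  }
  attr(out, "rTiers") <- rTiers
  out
}

#' Tract overlap proportions with subtype maps
#'
#' For each tract and subtype, the fraction of tract voxels falling inside
#' the subtype's suprathreshold region (z > `zThresh`, the permissive
#' display threshold by default). Rows need not sum to 1: subtypes overlap
#' and tracts may traverse unassigned tissue.
#'
#' @param atlas a [SubtypeAtlas-class] or named list of z-map arrays.
#' @param tracts named list of logical tract masks.
#' @param zThresh threshold applied to the subtype z-maps.
#' @return matrix tracts x subtypes of proportions in `[0, 1]`.
#' @export
tractOverlapProportions <- function(atlas, tracts, zThresh = 2) {
  zmaps <- if (is(atlas, "SubtypeAtlas")) atlas@zMaps else atlas
  sizes <- vapply(tracts, sum, numeric(1))
  if (any(sizes == 0)) stop("empty tract: ",
                            paste(names(tracts)[sizes == 0], collapse = ", "))
  out <- matrix(NA_real_, length(tracts), length(zmaps),
                dimnames = list(names(tracts), names(zmaps)))
  for (i in seq_along(tracts)) for (j in seq_along(zmaps)) {
    sup <- !is.na(zmaps[[j]]) & zmaps[[j]] > zThresh
    out[i, j] <- sum(tracts[[i]] & sup) / sizes[i]
  }
  out
}
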