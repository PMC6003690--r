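#' Match components across decompositions of different model order
#'
#' The reference run is the one with the smallest model order among those
#' with the fullest selection (most components). Every other run is matched
#' to the reference by the optimal one-to-one assignment maximizing total
#' absolute spatial correlation of z-maps (exact assignment by subset
#' dynamic programming). Matched pairs with correlation below `rMin` are
#' flagged unstable; surplus components are reported as unmatched.
#'
#' @param runs list of [ComponentSet-class] objects on the same mask.
#' @param rMin correlation below which a matched pair is flagged unstable.
#' @return list: `reference` (index into `runs`), `assignments` (data.frame
#'   run/refComponent/runComponent/r/unstable), `stacks` (per reference
#'   component, a runs x voxels matrix of sign-aligned z-maps),
#'   `unmatched` (data.frame run/component).
#' @export
matchComponentsAcrossRuns <- function(runs, rMin = 0.3) {
  stopifnot(length(runs) >= 2L)
  vi <- runs[[1]]@voxelIndex
  for (r in runs) if (!identical(r@voxelIndex, vi))
    stop("runs must share the analysis mask")
  nsel <- vapply(runs, function(r) nrow(r@sources), integer(1))
  orders <- vapply(runs, function(r) r@modelOrder, integer(1))
  ## reference = smallest model order among the runs with the consensus
  ## (modal) selection count, so a single over-selecting run cannot force
  ## a spurious reference subtype
  counts <- table(nsel)
  consensus <- as.integer(names(counts)[which.max(counts)])
  full <- which(nsel == consensus)
  ref <- full[which.min(orders[full])]
  nref <- nsel[ref]
  Sref <- runs[[ref]]@sources
  stacks <- lapply(seq_len(nref), function(i) {
    m <- matrix(NA_real_, length(runs), ncol(Sref))
    m[ref, ] <- Sref[i, ]
    m
  })
  assign <- data.frame()
  unmatched <- data.frame()
  for (k in seq_along(runs)) {
    if (k == ref) next
    Sk <- runs[[k]]@sources
    if (nrow(Sk) == 0L) {
      unmatched <- rbind(unmatched, data.frame(run = k, component = NA))
      next
    }
    R <- stats::cor(t(Sref), t(Sk))       # nref x nk
    nk <- nrow(Sk)
    if (nk >= nref) {
      sol <- assignmentMax(abs(R))
      pairs <- cbind(seq_len(nref), sol$assignment)
    } else {
      sol <- assignmentMax(t(abs(R)))
      pairs <- cbind(sol$assignment, seq_len(nk))
    }
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      r <- R[i, j]
      stacks[[i]][k, ] <- sign(r) * Sk[j, ]
      assign <- rbind(assign, data.frame(
        run = k, refComponent = i, runComponent = j, r = abs(r),
        unstable = abs(r) < rMin))
    }
    extra <- setdiff(seq_len(nk), pairs[, 2])
    if (length(extra))
      unmatched <- rbind(unmatched, data.frame(run = k, component = extra))
  }
  list(reference = ref, assignments = assign, stacks = stacks,
       unmatched = unmatched, voxelIndex = vi,
       gridDim = runs[[ref]]@gridDim, mask = runs[[ref]]@mask)
}

#' Fleiss' kappa for multi-rater binary maps
#'
#' Chance-corrected agreement among R raters over V items with two
#' categories. Items are voxels, raters are decompositions at different
#' model orders, categories are subtype / not-subtype.
#'
#' @param ratings logical (or 0/1) matrix, raters x items.
#' @return kappa. If expected agreement is 1 (all ratings in one category),
#'   kappa is 1 for perfect agreement and NaN (with a warning) otherwise.
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings) * 1
  R <- nrow(ratings); V <- ncol(ratings)
  if (R < 2L) stop("at least 2 raters are required")
  n1 <- colSums(ratings)            # raters voting category 1 per item
  n0 <- R - n1
  Pi <- (n1^2 + n0^2 - R) / (R * (R - 1))
  Pbar <- mean(Pi)
  p1 <- sum(n1) / (R * V); p0 <- 1 - p1
  Pe <- p1^2 + p0^2
  if (abs(1 - Pe) < 1e-12) {
    if (Pbar >= 1 - 1e-12) return(1)
    warning("degenerate category distribution; kappa undefined")
    return(NaN)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Average matched components into a subtype atlas
#'
#' Voxelwise mean of the matched z-maps per subtype, re-standardized over
#' the analysis mask. Fleiss' kappa across runs is computed per subtype at
#' both the display (z >= 2) and extraction (z >= 3.2) thresholds; a
#' cluster-extent filter (k voxels, 26-connectivity) is applied to the
#' display maps only. Pairwise Dice overlap of the subtype display masks is
#' reported (subtypes are expected to overlap only marginally).
#'
#' @param matched output of [matchComponentsAcrossRuns()].
#' @param zDisplay,zExtract display and extraction z thresholds.
#' @param clusterK minimum cluster extent (voxels) for display maps.
#' @param subtypeNames optional names for the subtypes.
#' @return a [SubtypeAtlas-class].
#' @export
averageMatchedComponents <- function(matched, zDisplay = 2, zExtract = 3.2,
                                     clusterK = 200L, subtypeNames = NULL) {
  stacks <- matched$stacks
  ns <- length(stacks)
  nm <- subtypeNames %||% paste0("subtype", seq_len(ns))
  gd <- matched$gridDim; vi <- matched$voxelIndex
  zMaps <- list(); disp <- list()
  kap <- data.frame()
  for (i in seq_len(ns)) {
    st <- stacks[[i]]
    st <- st[rowSums(is.na(st)) == 0L, , drop = FALSE]
    if (nrow(st) < 2L) {
      warning("subtype ", nm[i], " matched in fewer than 2 runs; dropped")
      next
    }
    avg <- colMeans(st)
    avg <- (avg - mean(avg)) / sqrt(mean((avg - mean(avg))^2))
    vol <- array(NA_real_, gd); vol[vi] <- avg
    zMaps[[nm[i]]] <- vol
    for (th in c(zDisplay, zExtract)) {
      k <- fleissKappa(st >= th)
      kap <- rbind(kap, data.frame(subtype = nm[i], threshold = th,
                                   kappa = k, nRuns = nrow(st)))
    }
    dm <- array(FALSE, gd)
    dm[vi] <- avg >= zDisplay
    disp[[nm[i]]] <- clusterExtentFilter(dm, clusterK)
  }
  kept <- names(zMaps)
  nk <- length(kept)
  dice <- matrix(NA_real_, nk, nk, dimnames = list(kept, kept))
  for (i in seq_len(nk)) for (j in seq_len(nk)) {
    a <- zMaps[[i]][vi] >= zDisplay; b <- zMaps[[j]][vi] >= zDisplay
    dice[i, j] <- 2 * sum(a & b) / max(sum(a) + sum(b), 1L)
  }
  memberZ <- stats::setNames(stacks, nm)[kept]
  new("SubtypeAtlas", zMaps = zMaps, displayMaps = disp, kappa = kap,
      dice = dice,
      thresholds = list(zDisplay = zDisplay, zExtract = zExtract,
                        clusterK = as.integer(clusterK)),
      memberZ = memberZ, voxelIndex = vi, gridDim = gd,
      mask = matched$mask)
}
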