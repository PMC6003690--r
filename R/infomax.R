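## Information-maximization spatial ICA. The group matrix rows (maps) are
## PCA-reduced and whitened, and an unmixing matrix is learned by the
## natural-gradient infomax rule with logistic nonlinearity, block updates,
## an annealed learning rate, and seeded restarts on divergence.

infomaxUnmix <- function(Xw, maxit = 512L, tol = 1e-7, lrate = 0.01) {
  N <- nrow(Xw); V <- ncol(Xw)
  block <- max(8L, ceiling(sqrt(V / 3)))
  W <- diag(N) + 0.01 * matrix(stats::rnorm(N * N), N)
  I <- diag(N)
  oldDelta <- Inf
  for (it in seq_len(maxit)) {
    Wold <- W
    perm <- sample.int(V)
    starts <- seq(1L, V, by = block)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + block - 1L, V)]
      u <- W %*% Xw[, idx, drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (I + ((1 - 2 * y) %*% t(u)) / length(idx)) %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) return(NULL)  # blow-up
    }
    delta <- sum((W - Wold)^2) / sum(Wold^2)
    if (delta < tol) break
    if (delta > oldDelta * 1.2) lrate <- lrate * 0.9  # oscillation: anneal
    oldDelta <- delta
  }
  W
}

#' Spatial ICA of a group matrix by infomax
#'
#' PCA pre-whitening to `nComponents` dimensions followed by
#' natural-gradient information-maximization ICA (logistic nonlinearity,
#' block updates, annealed learning rate, weight-change stopping rule,
#' bounded seeded restarts on divergence). Sources are z-scored over the
#' analysis mask, sign-fixed to non-negative skewness, and ordered by
#' variance explained. Per-component selection statistics (the
#' between-parameter over between-subject loading-SD ratio, and variance
#' explained) are attached.
#'
#' @param gm a [GroupMatrix-class].
#' @param nComponents model order N (reduced if the matrix rank is lower).
#' @param seed RNG seed; the decomposition is deterministic given the seed.
#' @param maxit,tol infomax stopping parameters.
#' @param maxRestarts restarts with a new seeded initialization on
#'   divergence before failing.
#' @return a [ComponentSet-class].
#' @export
runSpatialIca <- function(gm, nComponents, seed = 1L, maxit = 512L,
                          tol = 1e-7, maxRestarts = 5L) {
  stopifnot(is(gm, "GroupMatrix"))
  X <- gm@data
  n <- nrow(X); V <- ncol(X)
  if (nComponents > n) stop("nComponents must not exceed the row count")
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / V
  eg <- eigen(C, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  N <- min(nComponents, rank)
  if (N < nComponents)
    warning("matrix rank ", rank, " below requested order; using N = ", N)
  Ev <- eg$vectors[, seq_len(N), drop = FALSE]
  dv <- eg$values[seq_len(N)]
  K <- diag(1 / sqrt(dv), N) %*% t(Ev)
  Xw <- K %*% Xc
  W <- withSeed(seed, {
    res <- NULL
    for (r in seq_len(maxRestarts)) {
      res <- infomaxUnmix(Xw, maxit = maxit, tol = tol,
                          lrate = 0.01 / (1.5^(r - 1)))
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(W)) stop("infomax failed to converge after seeded restarts")
  S <- W %*% Xw                          # N x V sources
  A <- Ev %*% diag(sqrt(dv), N) %*% solve(W)  # n x N mixing
  ## z-score sources; push scale into the mixing matrix
  mu <- rowMeans(S)
  sdv <- sqrt(rowMeans((S - mu)^2))
  S <- (S - mu) / sdv
  A <- A * rep(sdv, each = n)
  ## sign convention: non-negative skewness
  sk <- apply(S, 1, skewness)
  flip <- sk < 0
  S[flip, ] <- -S[flip, ]
  A[, flip] <- -A[, flip]
  tot <- sum(Xc^2)
  ve <- colSums(A^2) * V / tot
  ord <- order(ve, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
  ratio <- vapply(seq_len(N), function(i)
    paramSubjectRatio(A[, i], gm@rowIndex), numeric(1))
  stats <- data.frame(component = seq_len(N), ratio = ratio,
                      wmOverlap = NA_real_, varExplained = ve[ord],
                      skewness = apply(S, 1, skewness))
  new("ComponentSet", sources = S, loadings = A, rowIndex = gm@rowIndex,
      stats = stats, voxelIndex = gm@voxelIndex, gridDim = gm@gridDim,
      mask = gm@mask, modelOrder = as.integer(nComponents),
      seed = as.integer(seed))
}

#' Subset a ComponentSet
#'
#' @param cs a [ComponentSet-class].
#' @param idx component indices to keep.
#' @return a [ComponentSet-class] with the selected components.
#' @export
subsetComponents <- function(cs, idx) {
  cs@sources <- cs@sources[idx, , drop = FALSE]
  cs@loadings <- cs@loadings[, idx, drop = FALSE]
  cs@stats <- cs@stats[idx, , drop = FALSE]
  cs
}
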