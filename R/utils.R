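## Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
wrapPhase <- function(x) {
  w <- x %% (2 * pi)          # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  ## map -pi (from w == pi case already handled) -- w in (-pi, pi]
  w
}

## Sample skewness (biased form; only the sign is used downstream).
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Exact solution of the linear assignment problem (maximise total score)
## by dynamic programming over column subsets: O(n^2 2^n), exact for the
## small component counts matched here (n <= ~15).
assignmentMax <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  stopifnot(n <= m, m <= 20L)
  nset <- bitwShiftL(1L, m)
  NEG <- -Inf
  best <- rep(NEG, nset)
  from <- integer(nset)
  pick <- integer(nset)
  best[1L] <- 0
  ## process rows in order; states with popcount(k) = r correspond to rows 1..r
  pop <- integer(nset)
  for (k in seq_len(nset - 1L)) pop[k + 1L] <- pop[bitwShiftR(k, 1) + 1L] + (k %% 2L)
  ord <- order(pop)
  for (pos in ord) {
    k <- pos - 1L
    r <- pop[k + 1L]
    if (r >= n || !is.finite(best[k + 1L])) next
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(k, bit) != 0L) next
      k2 <- bitwOr(k, bit)
      v <- best[k + 1L] + score[r + 1L, j]
      if (v > best[k2 + 1L]) {
        best[k2 + 1L] <- v
        from[k2 + 1L] <- k
        pick[k2 + 1L] <- j
      }
    }
  }
  ## best full assignment over states with popcount == n
  cand <- which(pop == n) - 1L
  kbest <- cand[which.max(best[cand + 1L])]
  assign <- integer(n)
  k <- kbest
  while (k != 0L) {
    r <- pop[k + 1L]
    assign[r] <- pick[k + 1L]
    k <- from[k + 1L]
  }
  list(assignment = assign, total = best[kbest + 1L])
}

## Quasi-uniform unit directions on the sphere (Fibonacci lattice),
## used as the default diffusion gradient scheme.
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## 26-connectivity cluster labelling of a logical 3D array.
## Pads the volume by one voxel so neighbour offsets never wrap across faces,
## then grows each cluster by vectorized frontier expansion.
labelClusters <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  big <- array(FALSE, dp)
  big[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offg <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offg <- offg[rowSums(abs(offg)) > 0, , drop = FALSE]
  offs <- offg[, 1] + dp[1] * offg[, 2] + dp[1] * dp[2] * offg[, 3]
  lab <- array(0L, dp)
  todo <- which(big)
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[big[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  array(lab[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)], d)
}

## Drop connected clusters smaller than kmin voxels (26-connectivity).
clusterExtentFilter <- function(mask, kmin) {
  lab <- labelClusters(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  sizes <- tabulate(lab)
  keep <- which(sizes >= kmin)
  array(lab %in% keep, dim(mask))
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop("grid mismatch between ", what, ": ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
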