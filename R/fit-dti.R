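#' Fit the diffusion tensor and derive its scalar maps
#'
#' Log-linear least-squares fit of the six-component symmetric tensor per
#' voxel, followed by eigendecomposition. Eigenvalues are sorted descending
#' and clipped at zero before scalar computation: AD = lambda1,
#' RD = (lambda2 + lambda3)/2, ADC = mean(lambda), FA by the normalized
#' eigenvalue-dispersion formula. A rank-deficient gradient design
#' (collinear directions) is rejected.
#'
#' @param dwi 4D array (x, y, z, acquisition) of diffusion-weighted signals.
#' @param params a [dtiParams()] descriptor; needs >= 1 b = 0 volume and
#'   >= 6 non-collinear diffusion directions.
#' @inheritParams fitR2Star
#' @return list of [ParameterMap()] objects: `AD`, `RD`, `ADC`, `FA`
#'   (diffusivities in um^2/s).
#' @export
fitDtiTensor <- function(dwi, params = dtiParams(),
                         subjectId = "unknown", voxelSize = 2) {
  d <- dim(dwi)
  if (length(d) != 4L) stop("dwi must be 4D (x, y, z, acquisition)")
  b <- params$bvals
  g <- params$bvecs
  if (d[4] != length(b)) stop("acquisition count does not match bvals")
  if (sum(b == 0) < 1L) stop("at least one b = 0 volume is required")
  if (sum(b > 0) < 6L) stop("at least 6 diffusion directions are required")
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7L) stop("rank-deficient gradient design (collinear directions)")
  S <- matrix(dwi, ncol = d[4])
  ok <- rowSums(!is.finite(S) | S <= 0) == 0L
  nv <- nrow(S)
  out <- list(AD = rep(NaN, nv), RD = rep(NaN, nv),
              ADC = rep(NaN, nv), FA = rep(NaN, nv))
  if (any(ok)) {
    beta <- qr.coef(qrX, t(log(S[ok, , drop = FALSE])))  # 7 x voxels, mm^2/s
    Dx <- t(beta[-1, , drop = FALSE]) * 1e6              # voxels x 6, um^2/s
    ev <- matrix(NA_real_, nrow(Dx), 3)
    for (i in seq_len(nrow(Dx))) {
      Dm <- matrix(c(Dx[i, 1], Dx[i, 4], Dx[i, 5],
                     Dx[i, 4], Dx[i, 2], Dx[i, 6],
                     Dx[i, 5], Dx[i, 6], Dx[i, 3]), 3, 3)
      ev[i, ] <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
    }
    ev <- pmax(ev, 0)                                    # clip negatives
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    md <- (l1 + l2 + l3) / 3
    ssq <- l1^2 + l2^2 + l3^2
    fa <- sqrt(1.5 * ((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2) /
                 pmax(ssq, 1e-30))
    fa[ssq <= 0] <- 0
    out$AD[ok] <- l1
    out$RD[ok] <- (l2 + l3) / 2
    out$ADC[ok] <- md
    out$FA[ok] <- pmin(fa, 1)
  }
  lapply(stats::setNames(names(out), names(out)), function(p)
    ParameterMap(array(out[[p]], d[1:3]), p, subjectId, voxelSize))
}
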