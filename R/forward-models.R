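## Forward signal models. These generate the raw multi-contrast volumes of
## the synthetic cohort and serve as the round-trip partners of the fitters.

#' Spoiled gradient-echo (SPGR) steady-state signal
#'
#' @param t1_s longitudinal relaxation time in seconds (vector ok).
#' @param tr_ms repetition time in ms.
#' @param fa_deg actual flip angle in degrees (vector ok).
#' @param m0 equilibrium magnetization scale.
#' @return signal magnitude (same shape as inputs after recycling).
#' @export
spgrSignal <- function(t1_s, tr_ms, fa_deg, m0 = 1) {
  e1 <- exp(-(tr_ms / 1000) / t1_s)
  a <- fa_deg * pi / 180
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Multi-echo gradient-echo magnitude decay
#'
#' @param s0 signal at TE = 0.
#' @param r2star effective transverse relaxation rate in s^-1.
#' @param te_ms echo times in ms.
#' @return matrix voxels x echoes (or vector if one voxel).
#' @export
mgreSignal <- function(s0, r2star, te_ms) {
  out <- outer(as.vector(r2star), te_ms / 1000, function(r, t) exp(-r * t))
  out <- out * as.vector(s0)
  if (nrow(out) == 1L) drop(out) else out
}

#' AFI signal ratio for a given actual flip angle
#'
#' Short-TR approximation of the dual-TR actual flip-angle steady state:
#' r = S2/S1 = (1 + n cos(theta)) / (n + cos(theta)).
#'
#' @param fa_actual_deg actual flip angle in degrees.
#' @param n the TR2/TR1 ratio.
#' @return the S2/S1 ratio.
#' @export
afiSignalRatio <- function(fa_actual_deg, n) {
  ca <- cos(fa_actual_deg * pi / 180)
  (1 + n * ca) / (n + ca)
}

## ---------------------------------------------------------------------------
## Two-pool pulsed magnetization-transfer model
## ---------------------------------------------------------------------------

## Super-Lorentzian absorption lineshape (seconds), offset in Hz.
## Midpoint quadrature over the orientation angle; adequate away from
## resonance (the MT offset is in the kHz range).
superLorentzianG <- function(delta_hz, t2b_s, nq = 256L) {
  th <- (seq_len(nq) - 0.5) * (pi / 2) / nq
  u <- 3 * cos(th)^2 - 1
  w <- sin(th) * (pi / 2) / nq
  ## outer over offsets
  x <- outer(2 * pi * delta_hz * t2b_s, 1 / u)     # offsets x nodes
  g <- exp(-2 * x^2)
  sqrt(2 / pi) * t2b_s * as.vector(g %*% (w / abs(u)))
}

## Lorentzian direct-saturation rate of the free pool (s^-1).
lorentzianWf <- function(w1rms2, delta_hz, t2f_s) {
  w1rms2 * t2f_s / (1 + (2 * pi * delta_hz * t2f_s)^2)
}

## RMS amplitude moments of a Gaussian pulse truncated at +-2.5 sigma.
## p1 = mean(shape), p2 = mean(shape^2) for a unit-peak envelope.
gaussianPulseMoments <- function(cutoff = 2.5, n = 4096L) {
  tau <- (seq_len(n) - 0.5) / n            # normalized time in [0, 1]
  s <- exp(-((tau - 0.5) * 2 * cutoff)^2 / 2)
  c(p1 = mean(s), p2 = mean(s^2))
}

## e^{A t} and (e^{A t} - I) A^{-1} c for stacks of 2x2 matrices with real
## distinct eigenvalues, vectorized over voxels. A given as columns a,b,c,d
## for [[a, b], [c, d]].
expm2Propagate <- function(a, b, c, d, t, cf, cb, M) {
  tr <- a + d
  det <- a * d - b * c
  disc <- sqrt(pmax(tr^2 / 4 - det, 1e-30))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  e1 <- exp(l1 * t); e2 <- exp(l2 * t)
  den <- l1 - l2
  ## e^{At} = e1 (A - l2 I)/den - e2 (A - l1 I)/den
  E11 <- (e1 * (a - l2) - e2 * (a - l1)) / den
  E12 <- (e1 - e2) * b / den
  E21 <- (e1 - e2) * c / den
  E22 <- (e1 * (d - l2) - e2 * (d - l1)) / den
  ## q = A^{ -1 } c
  q1 <- (d * cf - b * cb) / det
  q2 <- (-c * cf + a * cb) / det
  ## M(t) = E (M + q) - q
  x1 <- M[, 1] + q1; x2 <- M[, 2] + q2
  cbind(E11 * x1 + E12 * x2 - q1,
        E21 * x1 + E22 * x2 - q2)
}

#' Steady-state MT-weighted to reference signal ratio of the two-pool model
#'
#' Pulsed magnetization-transfer steady state for an SPGR readout preceded by
#' an off-resonance Gaussian saturation pulse, propagated with 2x2 matrix
#' exponentials and the continuous-wave RMS approximation of the pulse.
#' The reference signal is the same sequence without saturation, so the
#' ratio is independent of M0 and receiver gain.
#'
#' @param f bound-pool fraction in `[0, 1)` (vectorized over voxels).
#' @param r1_s observed longitudinal rate R1 = 1/T1 in s^-1 (recycled).
#' @param b0_hz static field offset in Hz (recycled).
#' @param b1 relative transmit field (recycled).
#' @param params an [mtParams()] descriptor.
#' @param constraints a [twoPoolConstraints()] set.
#' @return S_MT / S_ref, same length as `f`.
#' @export
mtSignalRatio <- function(f, r1_s, b0_hz = 0, b1 = 1,
                          params = mtParams(),
                          constraints = twoPoolConstraints()) {
  n <- length(f)
  r1 <- rep_len(r1_s, n); b0 <- rep_len(b0_hz, n); b1v <- rep_len(b1, n)
  tm <- params$pulse_duration_ms / 1000
  tr <- params$tr_ms / 1000
  ts <- 0.0003                       # gap between pulse end and excitation
  td <- tr - tm - ts
  mom <- gaussianPulseMoments()
  fa_eff <- params$fa_mt_deg * pi / 180 * b1v
  w1max <- fa_eff / (mom["p1"] * tm)
  w1rms2 <- w1max^2 * mom["p2"]
  delta <- params$offset_hz - b0
  t2b <- constraints$t2b_us * 1e-6
  t2f <- constraints$t2f_over_t1 / r1
  kb <- rep_len(constraints$k_combined, n)   # bound -> free exchange (s^-1)
  kf <- kb * f / (1 - f)                     # free -> bound
  Wb <- pi * w1rms2 * superLorentzianG(delta, t2b)
  Wf <- lorentzianWf(w1rms2, delta, t2f)
  thr <- params$readout_fa_deg * pi / 180 * b1v
  m0f <- 1 - f; m0b <- f

  ## closed-form fixed point of the per-TR affine cycle map: the cycle
  ## (after-readout -> decay td -> saturation pulse tm -> decay ts -> readout)
  ## is affine, M_pre = P M_after + q, so the steady state solves a 2x2
  ## linear system per voxel.
  cycleSignal <- function(satWb, satWf) {
    a0 <- -(r1 + kf); bm <- kb; c0 <- kf; d0 <- -(r1 + kb)
    cf <- r1 * m0f; cb <- r1 * m0b
    runCycle <- function(M) {
      M <- expm2Propagate(a0, bm, c0, d0, td, cf, cb, M)
      M <- expm2Propagate(a0 - satWf, bm, c0, d0 - satWb, tm, cf, cb, M)
      expm2Propagate(a0, bm, c0, d0, ts, cf, cb, M)
    }
    zero <- cbind(rep(0, n), rep(0, n))
    q <- runCycle(zero)
    Pe1 <- runCycle(cbind(rep(1, n), rep(0, n))) - q
    Pe2 <- runCycle(cbind(rep(0, n), rep(1, n))) - q
    ## after readout: M_after = diag(cos thr, 1) %*% M_pre
    ## fixed point: M_after = D (P M_after + q)
    ct <- cos(thr)
    A11 <- ct * Pe1[, 1]; A12 <- ct * Pe2[, 1]
    A21 <- Pe1[, 2];      A22 <- Pe2[, 2]
    r1v <- ct * q[, 1];   r2v <- q[, 2]
    det <- (1 - A11) * (1 - A22) - A12 * A21
    Maf1 <- ((1 - A22) * r1v + A12 * r2v) / det
    Maf2 <- (A21 * r1v + (1 - A11) * r2v) / det
    Mpre1 <- Pe1[, 1] * Maf1 + Pe2[, 1] * Maf2 + q[, 1]
    Mpre1 * sin(thr)
  }
  sMT <- cycleSignal(Wb, Wf)
  sRef <- cycleSignal(rep(0, n), rep(0, n))
  sMT / sRef
}

## ---------------------------------------------------------------------------
## pSSFP steady state (RF-spoiled gradient echo with quadratic phase cycling)
## ---------------------------------------------------------------------------

#' Steady-state pSSFP signal by isochromat Bloch simulation
#'
#' Simulates the RF-spoiled gradient-echo steady state for a quadratic RF
#' phase increment, averaging an isochromat ensemble that is dephased by one
#' full cycle per TR by the spoiler gradient. Returns the demodulated signal
#' magnitude directly after the excitation pulse (echo-time decay cancels in
#' the two-increment ratio).
#'
#' @param t2_s transverse relaxation times in seconds (vectorized).
#' @param t1_s longitudinal relaxation time in seconds (scalar or recycled).
#' @param fa_deg actual flip angle in degrees (scalar or recycled).
#' @param tr_ms repetition time in ms.
#' @param phi0_deg quadratic RF-spoiling phase increment in degrees.
#' @param n_iso number of isochromats across the voxel.
#' @param n_tr number of simulated repetitions.
#' @param n_avg number of trailing repetitions averaged for the steady value.
#' @return steady-state signal magnitude per `t2_s` entry.
#' @export
pssfpSignal <- function(t2_s, t1_s = 1.25, fa_deg = 60, tr_ms = 7,
                        phi0_deg = 1, n_iso = 96L, n_tr = 1200L,
                        n_avg = 100L) {
  nc <- length(t2_s)
  t1 <- rep_len(t1_s, nc); fa <- rep_len(fa_deg, nc) * pi / 180
  tr <- tr_ms / 1000
  e1 <- rep(exp(-tr / t1), each = n_iso)
  e2 <- rep(exp(-tr / t2_s), each = n_iso)
  sa <- rep(sin(fa), each = n_iso); ca <- rep(cos(fa), each = n_iso)
  th <- 2 * pi * ((seq_len(n_iso) - 0.5) / n_iso - 0.5)  # spoiler dephasing
  cg <- rep(cos(th), nc); sg <- rep(sin(th), nc)
  K <- nc * n_iso
  Mx <- numeric(K); My <- numeric(K); Mz <- rep(1, K)
  phi0 <- phi0_deg * pi / 180
  acc <- numeric(nc); first <- n_tr - n_avg + 1L
  grp <- rep(seq_len(nc), each = n_iso)
  for (j in seq_len(n_tr)) {
    phi <- phi0 * j * (j - 1) / 2
    cp <- cos(phi); sp <- sin(phi)
    ## rotate about axis (cos phi, sin phi, 0) by alpha:
    ## R = Rz(phi) Rx(alpha) Rz(-phi)
    u <- cp * Mx + sp * My          # component along axis
    v <- -sp * Mx + cp * My         # orthogonal transverse component
    v2 <- ca * v + sa * Mz
    z2 <- -sa * v + ca * Mz
    Mx <- cp * u - sp * v2
    My <- sp * u + cp * v2
    Mz <- z2
    if (j >= first) {
      sx <- Mx * cp + My * sp       # demodulate by RF phase
      sy <- -Mx * sp + My * cp
      re <- colMeans(matrix(sx, n_iso))
      im <- colMeans(matrix(sy, n_iso))
      acc <- acc + sqrt(re^2 + im^2)
    }
    ## relaxation over TR then spoiler gradient dephasing
    Mx <- Mx * e2; My <- My * e2
    Mz <- 1 + (Mz - 1) * e1
    x2 <- cg * Mx - sg * My
    My <- sg * Mx + cg * My
    Mx <- x2
  }
  acc / n_avg
}

#' Diffusion-weighted signals from tensor eigenstructure
#'
#' @param evals eigenvalues (lambda1 >= lambda2 >= lambda3) in um^2/s,
#'   one row per voxel.
#' @param evecs 3x3 rotation matrix whose columns are the eigenvectors
#'   (shared across voxels), or NULL for the identity.
#' @param params a [dtiParams()] descriptor.
#' @param s0 non-diffusion-weighted signal.
#' @return matrix voxels x acquisitions.
#' @export
dtiSignals <- function(evals, evecs = NULL, params = dtiParams(), s0 = 1000) {
  evals <- rbind(evals)
  if (is.null(evecs)) evecs <- diag(3)
  ## D = V diag(lambda) V', in mm^2/s
  g <- params$bvecs
  b <- params$bvals
  gq <- g %*% evecs                       # directions in eigenframe
  ## b g' D g = b sum_k lambda_k (g.v_k)^2
  quad <- (gq^2) %*% t(evals * 1e-6)      # acquisitions x voxels
  t(s0 * exp(-b * quad))
}
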