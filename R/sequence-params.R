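## Acquisition descriptors. Defaults reproduce the 3T protocol the forward
## models and fitters were designed around; every field can be overridden.

#' Sequence parameter descriptors
#'
#' Constructors for the acquisition descriptors consumed by the forward
#' models and fitters. Defaults correspond to the protocol the package's
#' forward simulations emulate.
#'
#' @param echo_times_ms echo times in ms (MGRE), strictly increasing.
#' @return a classed list of acquisition parameters.
#' @name sequenceParams
NULL

#' @rdname sequenceParams
#' @export
mgreParams <- function(echo_times_ms = seq(2.21, by = 3.7, length.out = 8)) {
  stopifnot(length(echo_times_ms) >= 2, all(diff(echo_times_ms) > 0))
  structure(list(echo_times_ms = echo_times_ms),
            class = c("MGREParams", "SequenceParams"))
}

#' @rdname sequenceParams
#' @param tr_ms repetition time in ms.
#' @param flip_angles_deg the two nominal SPGR flip angles in degrees.
#' @export
vfaParams <- function(tr_ms = 20, flip_angles_deg = c(4, 25)) {
  stopifnot(length(flip_angles_deg) == 2, tr_ms > 0)
  structure(list(tr_ms = tr_ms, flip_angles_deg = flip_angles_deg),
            class = c("VFAParams", "SequenceParams"))
}

#' @rdname sequenceParams
#' @param tr1_ms,tr2_ms the two AFI repetition times (tr2 an integer multiple
#'   of tr1); defaults give TR1 + TR2 = 111 ms with TR2 = 5 TR1.
#' @param nominal_fa_deg nominal AFI flip angle in degrees.
#' @export
afiParams <- function(tr1_ms = 18.5, tr2_ms = 92.5, nominal_fa_deg = 60) {
  n <- tr2_ms / tr1_ms
  if (abs(n - round(n)) > 1e-6 || round(n) < 2)
    stop("tr2/tr1 must be an integer n >= 2")
  structure(list(tr1_ms = tr1_ms, tr2_ms = tr2_ms,
                 nominal_fa_deg = nominal_fa_deg, n = round(n)),
            class = c("AFIParams", "SequenceParams"))
}

#' @rdname sequenceParams
#' @param pulse_duration_ms MT saturation pulse duration (Gaussian envelope).
#' @param fa_mt_deg MT saturation flip angle in degrees.
#' @param offset_hz MT off-resonance offset in Hz.
#' @param readout_fa_deg excitation flip angle of the MT-weighted readout.
#' @param te_pair_ms the two echo times used for the B0 phase difference.
#' @export
mtParams <- function(pulse_duration_ms = 12, fa_mt_deg = 560, offset_hz = 6000,
                     tr_ms = 28, readout_fa_deg = 6, te_pair_ms = c(2.25, 6.90)) {
  stopifnot(length(te_pair_ms) == 2)
  structure(list(pulse_duration_ms = pulse_duration_ms, pulse_shape = "gaussian",
                 fa_mt_deg = fa_mt_deg, offset_hz = offset_hz, tr_ms = tr_ms,
                 readout_fa_deg = readout_fa_deg, te_pair_ms = te_pair_ms),
            class = c("MTParams", "SequenceParams"))
}

#' @rdname sequenceParams
#' @param te_ms echo time in ms.
#' @param fa_deg nominal flip angle in degrees.
#' @param spoil_increments_deg the two quadratic RF-spoiling phase increments
#'   in degrees (a nearly coherent and a strongly spoiled acquisition).
#' @param assumed_t1_s the fixed global T1 (s) assumed when inverting for T2.
#' @param t2_cap_ms ceiling applied to fitted T2 values (ms).
#' @export
pssfpParams <- function(tr_ms = 7, te_ms = 3, fa_deg = 60,
                        spoil_increments_deg = c(1, 20),
                        assumed_t1_s = 1.25, t2_cap_ms = 150) {
  stopifnot(length(spoil_increments_deg) == 2)
  structure(list(tr_ms = tr_ms, te_ms = te_ms, fa_deg = fa_deg,
                 spoil_increments_deg = spoil_increments_deg,
                 assumed_t1_s = assumed_t1_s, t2_cap_ms = t2_cap_ms),
            class = c("PSSFPParams", "SequenceParams"))
}

#' @rdname sequenceParams
#' @param bvals b-values in s/mm^2 (>= 1 zero entry required for fitting).
#' @param bvecs unit gradient directions, one row per bval.
#' @export
dtiParams <- function(bvals = c(0, rep(1500, 20)),
                      bvecs = rbind(c(0, 0, 0), fibonacciDirections(20))) {
  bvecs <- as.matrix(bvecs)
  stopifnot(nrow(bvecs) == length(bvals), ncol(bvecs) == 3)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("b-vectors must be unit norm for b > 0")
  structure(list(bvals = bvals, bvecs = bvecs),
            class = c("DTIParams", "SequenceParams"))
}

#' Two-pool constraint set for single-point MPF fitting
#'
#' The constrained nuisance parameters of the two-pool magnetization-transfer
#' model: bound-pool T2 (µs), the T2f/T1 ratio, the combined exchange rate
#' k(1-f)/f (s^-1), and the flag tying R1f = R1b to the measured R1.
#'
#' @param t2b_us bound-pool T2 in microseconds.
#' @param t2f_over_t1 free-pool T2 as a fraction of T1.
#' @param k_combined k(1-f)/f in s^-1 (the bound-to-free exchange rate).
#' @param r1_coupling logical; constrain R1f = R1b = measured R1.
#' @return a classed list of constraints.
#' @export
twoPoolConstraints <- function(t2b_us = 9.7, t2f_over_t1 = 0.022,
                               k_combined = 19, r1_coupling = TRUE) {
  stopifnot(t2b_us > 0, t2f_over_t1 > 0, k_combined > 0)
  structure(list(t2b_us = t2b_us, t2f_over_t1 = t2f_over_t1,
                 k_combined = k_combined, r1_coupling = r1_coupling),
            class = "TwoPoolConstraints")
}
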