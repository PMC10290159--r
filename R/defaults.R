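#' Default clock-network parameters
#'
#' Rate constants of the transcription-translation network, calibrated so
#' that the wild-type system is a self-sustained limit-cycle oscillator
#' with a free-running period of 23.8 h in which every mRNA in the fitted
#' gene panel oscillates with a relative amplitude above the 5% fitting
#' constraint (minimum ~0.16, ARNTL ~0.39). Units: maximal transcription
#' rates in concentration/h, all first-order rates in 1/h, activation and
#' inhibition constants in the concentration units of the nuclear protein
#' pools, Hill coefficients dimensionless.
#'
#' `vmax_PER` is the light-sensitive maximal transcription rate targeted
#' by the light Zeitgeber; `vmax_NR1D` is the target of
#' pharmacological/feeding pulses. `ki_NR1D_ARNTL` and `ki_NR1D_CLOCK` are
#' the inhibition constants of NR1D on ARNTL and CLOCK; `dn_*` are the
#' nuclear protein degradation rates.
#'
#' @return named numeric vector matching
#'   `build_network(default_topology())$param_names`.
#' @export
default_clock_parameters <- function() {
  c(
    vmax_ARNTL = 2.52295, vmax_CLOCK = 0.447505, vmax_PER = 0.953087,
    vmax_CRY = 0.340593, vmax_NR1D = 0.21421, vmax_ROR = 2.02233,
    vmax_DBP = 1.49991, vmax_NFIL3 = 0.95301, vmax_PPARA = 0.529658,
    vmax_CES2 = 1.59663, vmax_ABCB = 2.99476, vmax_ABCC = 0.700637,
    vmax_UGT1A1 = 0.193287,
    dm_ARNTL = 1.03539, dm_CLOCK = 0.262159, dm_PER = 0.238864,
    dm_CRY = 0.268843, dm_NR1D = 0.101015, dm_ROR = 0.737936,
    dm_DBP = 0.270292, dm_NFIL3 = 0.645662, dm_PPARA = 0.598723,
    dm_CES2 = 0.294968, dm_ABCB = 0.347418, dm_ABCC = 0.0712971,
    dm_UGT1A1 = 0.809642,
    ktl_ARNTL = 0.861799, ktl_CLOCK = 2.88796, ktl_PER = 0.213645,
    ktl_CRY = 2.26684, ktl_NR1D = 1.00156, ktl_ROR = 0.784136,
    ktl_DBP = 1.73635, ktl_NFIL3 = 0.64983, ktl_PPARA = 0.312619,
    kim_ARNTL = 0.30145, kim_CLOCK = 0.968841, kim_PER = 0.223159,
    kim_CRY = 0.133069, kim_NR1D = 0.0565542, kim_ROR = 1.23505,
    kim_DBP = 0.112967, kim_NFIL3 = 0.3383, kim_PPARA = 0.417608,
    dc_ARNTL = 0.114064, dc_CLOCK = 0.55838, dc_PER = 0.0476309,
    dc_CRY = 0.0660632, dc_NR1D = 0.453661, dc_ROR = 0.374477,
    dc_DBP = 0.5167, dc_NFIL3 = 0.49009, dc_PPARA = 0.293777,
    dn_ARNTL = 0.662501, dn_CLOCK = 0.137811, dn_PER = 0.273698,
    dn_CRY = 0.311362, dn_NR1D = 0.634278, dn_ROR = 0.308093,
    dn_DBP = 1.0032, dn_NFIL3 = 0.142064, dn_PPARA = 0.935224,
    ka_ebox = 1.25778, ki_cplx = 0.130834,
    hill_act = 2, hill_inh = 2.5, hill_cplx = 6, basal = 0.15,
    kf_cplx = 0.0219821, kb_cplx = 0.162062, dn_cplx = 0.111463,
    ka_ROR_ARNTL = 6.39345, ki_NR1D_ARNTL = 2.37676,
    ka_ROR_CLOCK = 0.964464, ki_NR1D_CLOCK = 2.8853,
    ki_NFIL3_PER = 7.40144, ki_NR1D_CRY = 1.72753,
    ki_NFIL3_NR1D = 3.24819,
    ka_ROR_NFIL3 = 4.35968, ki_NR1D_NFIL3 = 2.7547,
    ka_DBP_PPARA = 0.902158,
    ka_DBP_CES2 = 3.14666, ki_PPARA_CES2 = 1.8602, ki_NR1D_CES2 = 0.568164,
    ka_DBP_ABCB = 0.751839, ki_NFIL3_ABCB = 0.785272,
    ka_DBP_ABCC = 0.91983, ki_NFIL3_ABCC = 11.5495,
    ka_DBP_UGT1A1 = 3.00056, ki_NFIL3_UGT1A1 = 1.69588
  )
}
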