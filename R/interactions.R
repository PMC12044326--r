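# Interaction primitives: competitive inhibition factor and the enzyme
# turnover/induction rate law. The dynamic engine evaluates these with
# time-varying local unbound perpetrator concentrations (gut enzymes see the
# enterocyte-exposure concentration, hepatic enzymes the unbound liver
# concentration).

#' Competitive inhibition factor
#'
#' Multiplier on an enzyme's (or transporter's) unbound intrinsic clearance
#' under competitive inhibition: `1 / (1 + cu / ki_u)` with
#' `ki_u = ki * fu_mic`, the inhibition constant corrected for nonspecific
#' binding in the microsomal incubation.
#'
#' @param cu Local unbound inhibitor concentration, µM (>= 0; vectorized).
#' @param ki Total inhibition constant, µM.
#' @param fu_mic Free fraction in the microsomal incubation (default 1).
#' @return Multiplier in (0, 1]; 1 at `cu = 0`, 0.5 at `cu = ki_u`.
#' @export
inhibition_factor <- function(cu, ki, fu_mic = 1) {
  stopifnot(all(cu >= 0), ki > 0, fu_mic > 0, fu_mic <= 1)
  1 / (1 + cu / (ki * fu_mic))
}

#' Enzyme turnover rate under induction
#'
#' First-order enzyme turnover with induced synthesis: `dE/dt = kdeg *
#' (E0 * (1 + ind_max * cu^h / (ind_c50^h + cu^h)) - E)`. At constant
#' inducer concentration the steady state is the bracketed fold-induction
#' times baseline; on washout activity returns to `E0` with rate `kdeg`.
#'
#' @param e Current relative enzyme activity.
#' @param e0 Baseline activity (1 = baseline).
#' @param kdeg Enzyme degradation rate constant, 1/h.
#' @param ind_max Maximal fold-induction minus baseline (unitless).
#' @param ind_c50 Unbound inducer concentration at half-maximal induction, µM.
#' @param cu Local unbound inducer concentration, µM.
#' @param hill Hill coefficient (default 1).
#' @return dE/dt, 1/h.
#' @export
induction_rate <- function(e, e0, kdeg, ind_max, ind_c50, cu, hill = 1) {
  stopifnot(kdeg > 0, ind_c50 > 0, ind_max >= 0, all(cu >= 0))
  fold <- 1 + ind_max * cu^hill / (ind_c50^hill + cu^hill)
  kdeg * (e0 * fold - e)
}
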