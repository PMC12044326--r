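# Closed-form DDI calculators: basic R-values, the mechanistic static AUC
# ratio, and the Ki,u sensitivity scan over the dynamic engine.

#' Mechanistic static AUC ratio
#'
#' The standard mechanistic static model for a victim drug:
#' `AUCR = [1 / (fg + (1 - fg) * f_gut)] * [1 / (sum fm_e * f_e + (1 - sum fm))]`
#' where `f_e` is the net inhibition-times-induction factor on hepatic enzyme
#' `e` at a fixed perpetrator concentration and `f_gut` the corresponding net
#' factor on intestinal intrinsic clearance. All factors 1 gives 1; pure
#' inhibition gives a ratio >= 1, pure induction <= 1. Used as a fast screen
#' and as an upper bound on dynamic simulations run at sub-maximal
#' perpetrator exposure.
#'
#' @param fm Named fractions of net metabolic clearance per hepatic enzyme.
#' @param fg Baseline intestinal availability (default 1 = no gut
#'   extraction).
#' @param f_hepatic Named factors on hepatic enzymes (names matching `fm`;
#'   missing enzymes keep factor 1).
#' @param f_gut Scalar net factor on intestinal intrinsic clearance.
#' @return List with `aucr`, `aucr_gut`, `aucr_hepatic` and the echoed inputs.
#' @export
mechanistic_static_aucr <- function(fm, fg = 1, f_hepatic = numeric(),
                                    f_gut = 1) {
  fm <- unlist(fm)
  stopifnot(all(fm >= 0), sum(fm) <= 1 + 1e-9, fg > 0, fg <= 1, f_gut >= 0)
  f_e <- rep(1, length(fm))
  names(f_e) <- names(fm)
  for (e in intersect(names(f_hepatic), names(fm))) f_e[e] <- f_hepatic[[e]]
  hep <- 1 / (sum(fm * f_e) + (1 - sum(fm)))
  gut <- 1 / (fg + (1 - fg) * f_gut)
  list(aucr = hep * gut, aucr_hepatic = hep, aucr_gut = gut,
       inputs = list(fm = fm, fg = fg, f_hepatic = f_e, f_gut = f_gut))
}

#' Basic R-value screen for reversible inhibition
#'
#' `R = 1 + I_u / Ki_u`: the regulatory first-tier ratio at a stated unbound
#' perpetrator concentration.
#'
#' @param i_u Unbound perpetrator concentration, µM.
#' @param ki Total inhibition constant, µM.
#' @param fu_mic Microsomal free fraction.
#' @return The R value (>= 1).
#' @export
r_value <- function(i_u, ki, fu_mic = 1) {
  stopifnot(i_u >= 0, ki > 0)
  1 + i_u / (ki * fu_mic)
}

#' Ki,u sensitivity scan
#'
#' Re-runs a DDI study with the perpetrator's unbound inhibition constants
#' divided by each fold value; fold 1 reproduces the unscaled study.
#'
#' @param design A [study_design()].
#' @param targets Character vector of inhibition targets to scale.
#' @param folds Numeric vector of fold-reductions (> 0).
#' @param ... Passed to [run_ddi_study()] (seed, system, tolerances...).
#' @return Data frame: one row per fold with AUC and Cmax GMRs and CIs.
#' @export
ki_sensitivity_scan <- function(design, targets, folds = c(1, 10), ...) {
  stopifnot(all(folds > 0))
  rows <- lapply(folds, function(f) {
    d <- design
    d$ki_scale <- stats::setNames(rep(f, length(targets)), targets)
    res <- run_ddi_study(d, ...)
    data.frame(fold = f,
               gmr_auc = res$gmr_auc[["gmr"]], auc_lo = res$gmr_auc[["lo"]],
               auc_hi = res$gmr_auc[["hi"]],
               gmr_cmax = res$gmr_cmax[["gmr"]], cmax_lo = res$gmr_cmax[["lo"]],
               cmax_hi = res$gmr_cmax[["hi"]])
  })
  do.call(rbind, rows)
}
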