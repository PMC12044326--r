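# Closed-form parameter derivations: permeability calibration, absorption
# rate/extent prediction, well-stirred organ clearance and its retrograde
# inversion, Michaelis-Menten intrinsic clearance, and Qgut first-pass
# availability. All functions are pure; units are fixed (see individual docs).

#' Fraction unbound in blood
#'
#' @param fu_plasma Fraction unbound in plasma (0, 1].
#' @param bp_ratio Blood:plasma concentration ratio (> 0).
#' @return Fraction unbound in blood, `fu_plasma / bp_ratio`. May exceed 1 for
#'   compounds excluded from blood cells.
#' @export
fu_blood <- function(fu_plasma, bp_ratio) {
  stopifnot(fu_plasma > 0, fu_plasma <= 1, bp_ratio > 0)
  fu_plasma / bp_ratio
}

#' Predict human jejunal effective permeability from Caco-2 permeability
#'
#' Log-linear calibration: reference-scale effective permeability is regressed
#' on log apparent permeability through the calibrator compounds measured in
#' the same Caco-2 system. With two calibrators (the usual low/high-permeability
#' anchor pair, e.g. atenolol and propranolol) the fit passes exactly through
#' both anchors, so a test compound whose Papp equals a calibrator's measured
#' value maps onto that calibrator's reference Peff.
#'
#' @param papp Apparent permeability of the test compound, 1e-6 cm/s.
#' @param calibrators Data frame with columns `name`, `papp` (measured in the
#'   same assay, 1e-6 cm/s) and `peff_ref` (reference-scale human jejunal
#'   permeability, 1e-4 cm/s). At least one row; with a single calibrator a
#'   unit log-log slope through that anchor is used.
#' @return Predicted effective human jejunal permeability, 1e-4 cm/s.
#' @export
predict_peff <- function(papp, calibrators) {
  stopifnot(is.numeric(papp), papp > 0)
  if (is.null(calibrators) || nrow(calibrators) < 1) {
    stop("no permeability calibrators supplied; provide an explicit peff_man instead")
  }
  stopifnot(all(c("papp", "peff_ref") %in% names(calibrators)),
            all(calibrators$papp > 0), all(calibrators$peff_ref > 0))
  lx <- log10(calibrators$papp)
  ly <- log10(calibrators$peff_ref)
  if (nrow(calibrators) == 1L) {
    a <- ly - lx  # unit slope anchor
    b <- 1
  } else {
    fit <- stats::lm.fit(cbind(1, lx), ly)
    a <- fit$coefficients[[1]]
    b <- fit$coefficients[[2]]
  }
  10^(a + b * log10(papp))
}

#' Predict first-order absorption rate and fraction absorbed from permeability
#'
#' The absorption rate constant follows from radial diffusion into the small
#' intestinal wall, `ka = 2 * Peff / R`, and the fraction absorbed from a
#' seven-compartment small-intestinal transit closed form
#' `fa = 1 - (1 + ka * T_si / 7)^-7`.
#'
#' @param peff Effective jejunal permeability, 1e-4 cm/s.
#' @param geometry List with `si_radius` (cm) and `si_transit` (h); a full
#'   system parameter list (see [default_system()]) works.
#' @return List with `ka` (1/h) and `fa` (fraction).
#' @export
predict_ka_fa <- function(peff, geometry) {
  stopifnot(peff >= 0)
  r <- geometry$si_radius
  tsi <- geometry$si_transit
  stopifnot(r > 0, tsi > 0)
  ka <- 2 * (peff * 1e-4) * 3600 / r
  fa <- 1 - (1 + ka * tsi / 7)^(-7)
  list(ka = ka, fa = fa)
}

#' Well-stirred organ clearance
#'
#' @param clu_int Unbound intrinsic clearance of the organ, L/h.
#' @param fu_b Fraction unbound in blood.
#' @param q_organ Organ blood flow, L/h.
#' @return Organ blood clearance `q * fu_b * clu_int / (q + fu_b * clu_int)`,
#'   L/h, always below `q_organ`.
#' @export
well_stirred_cl <- function(clu_int, fu_b, q_organ) {
  stopifnot(clu_int >= 0, fu_b >= 0, q_organ > 0)
  q_organ * fu_b * clu_int / (q_organ + fu_b * clu_int)
}

# Inverse of the well-stirred model: intrinsic clearance from organ clearance.
well_stirred_clint <- function(cl_organ, fu_b, q_organ) {
  stopifnot(cl_organ >= 0, cl_organ < q_organ, fu_b > 0)
  q_organ * cl_organ / (fu_b * (q_organ - cl_organ))
}

#' Michaelis-Menten unbound intrinsic clearance
#'
#' @param vmax Maximum rate, pmol/min/pmol isoform.
#' @param km Michaelis constant, µM (unbound).
#' @param cu Local unbound substrate concentration, µM. At `cu = 0` the
#'   clearance is the linear-region value `vmax / km`.
#' @return Intrinsic clearance `vmax / (km + cu)`, µL/min/pmol isoform.
#' @export
mm_clint <- function(vmax, km, cu = 0) {
  stopifnot(vmax >= 0, km > 0, all(cu >= 0))
  vmax / (km + cu)
}

#' Qgut first-pass intestinal availability
#'
#' @param qgut Hybrid flow term for drug delivery to the enterocyte, L/h.
#' @param fu_gut Fraction unbound in the enterocyte.
#' @param clu_int_gut Total intestinal unbound intrinsic clearance, L/h.
#' @return Fraction escaping gut first-pass metabolism,
#'   `qgut / (qgut + fu_gut * clu_int_gut)`.
#' @export
fg_qgut <- function(qgut, fu_gut, clu_int_gut) {
  stopifnot(qgut > 0, fu_gut >= 0, clu_int_gut >= 0)
  qgut / (qgut + fu_gut * clu_int_gut)
}

# Per-enzyme pool sizes (pmol) by tissue for one individual's system
# parameters: liver = abundance (pmol/mg) * MPPGL (mg/g) * liver weight (g);
# intestine = total pmol directly; kidney = abundance * MPPGK * kidney weight.
enzyme_pools <- function(system) {
  enz <- metabolic_enzymes()
  ab <- system$abundance
  get_ab <- function(e, tissue) {
    v <- ab[[e]][[tissue]]
    if (is.null(v)) return(0)
    v
  }
  liver <- vapply(enz, function(e) get_ab(e, "liver"), numeric(1)) *
    system$mppgl * system$liver_weight
  gut <- vapply(enz, function(e) get_ab(e, "intestine"), numeric(1))
  kidney <- vapply(enz, function(e) get_ab(e, "kidney"), numeric(1)) *
    system$mppgk * system$kidney_weight
  list(liver = liver, intestine = gut, kidney = kidney)
}

# Apply a compound's per-enzyme tissue scalars to pool sizes. `scalars` is a
# named map enzyme -> list(liver=, intestine=, kidney=); missing entries
# default to 1 (enzyme participates with full system abundance).
scaled_pools <- function(system, tissue_scalars = NULL) {
  pools <- enzyme_pools(system)
  if (!is.null(tissue_scalars)) {
    for (e in names(tissue_scalars)) {
      sc <- tissue_scalars[[e]]
      for (tis in names(sc)) {
        if (e %in% names(pools[[tis]])) pools[[tis]][[e]] <- pools[[tis]][[e]] * sc[[tis]]
      }
    }
  }
  pools
}

#' Retrograde derivation of per-isoform intrinsic clearance
#'
#' Inverts the well-stirred organ model to recover per-isoform unbound
#' intrinsic clearances (µL/min/pmol isoform) from an observed systemic
#' clearance. Metabolic clearance (`cl_iv - cl_renal`, plasma basis) is
#' converted to blood clearance and apportioned across isoforms in proportion
#' to their `fm` values; each isoform's per-pmol clearance acts in every
#' tissue where the system file gives it abundance (liver and, for the renal
#' UGTs, kidney), so the scalar apportionment is solved so that the forward
#' well-stirred liver + kidney clearances reproduce the observed metabolic
#' clearance exactly.
#'
#' @param cl_iv Observed systemic (plasma) clearance, L/h.
#' @param cl_renal Renal excretory (plasma) clearance, L/h, treated as purely
#'   excretory.
#' @param fu_b Fraction unbound in blood.
#' @param fm_map Named numeric vector/list of fractions of net metabolic
#'   clearance per enzyme; values >= 0, sum <= 1 (renormalized to the metabolic
#'   share they cover).
#' @param system System parameter list, see [default_system()].
#' @param bp_ratio Blood:plasma ratio used to convert plasma clearances to
#'   blood clearances (default 1).
#' @param tissue_scalars Optional per-enzyme tissue scalars (see compound
#'   elimination block).
#' @return Object of class `pbpk_clearances`: list with `per_enzyme_clu_int`
#'   (µL/min/pmol), `clu_int_hepatic` and `clu_int_renal` (L/h),
#'   `cl_hepatic_blood`, `cl_renal_met_blood` (L/h), `fu_blood` and `fh`.
#' @export
retrograde_clint <- function(cl_iv, cl_renal, fu_b, fm_map, system,
                             bp_ratio = 1, tissue_scalars = NULL) {
  fm <- unlist(fm_map)
  stopifnot(cl_iv > cl_renal, all(fm >= 0), sum(fm) <= 1 + 1e-9, fu_b > 0)
  cl_met_b <- (cl_iv - cl_renal) / bp_ratio
  if (cl_met_b >= system$q_hepatic + system$q_kidney) {
    stop("metabolic blood clearance exceeds total eliminating organ blood flow; ",
         "the well-stirred model cannot represent this compound")
  }
  pools <- scaled_pools(system, tissue_scalars)
  enz <- names(fm)[fm > 0]
  n_tot <- pools$liver[enz] + pools$kidney[enz]
  if (any(n_tot <= 0)) {
    stop("no liver/kidney abundance for enzyme(s): ",
         paste(enz[n_tot <= 0], collapse = ", "))
  }
  fm_use <- fm[enz]
  # per-pmol clearance c_e = s * fm_e / n_tot_e; find s so forward CL matches
  wliv <- sum(fm_use * pools$liver[enz] / n_tot) * UL_MIN_TO_L_H
  wkid <- sum(fm_use * pools$kidney[enz] / n_tot) * UL_MIN_TO_L_H
  forward <- function(s) {
    well_stirred_cl(s * wliv, fu_b, system$q_hepatic) +
      well_stirred_cl(s * wkid, fu_b, system$q_kidney) - cl_met_b
  }
  hi <- cl_met_b / (fu_b * (wliv + wkid)) * 2
  while (forward(hi) < 0) hi <- hi * 4
  s <- stats::uniroot(forward, c(0, hi), tol = 1e-13 * hi)$root
  # polish with one Newton-like bisection refinement via uniroot tolerance
  per_enzyme <- s * fm_use / n_tot
  clu_h <- s * wliv
  clu_r <- s * wkid
  cl_h <- well_stirred_cl(clu_h, fu_b, system$q_hepatic)
  cl_r <- well_stirred_cl(clu_r, fu_b, system$q_kidney)
  structure(list(
    per_enzyme_clu_int = per_enzyme,
    clu_int_hepatic = clu_h,
    clu_int_renal = clu_r,
    cl_hepatic_blood = cl_h,
    cl_renal_met_blood = cl_r,
    cl_met_blood = cl_met_b,
    fu_blood = fu_b,
    fh = 1 - cl_h / system$q_hepatic
  ), class = "pbpk_clearances")
}

#' Forward recomputation of metabolic blood clearance from per-isoform values
#'
#' Companion to [retrograde_clint()]: given per-isoform unbound intrinsic
#' clearances (µL/min/pmol), recomputes the total metabolic blood clearance by
#' the well-stirred liver and kidney models, for round-trip verification.
#'
#' @param per_enzyme_clu_int Named vector, µL/min/pmol isoform.
#' @inheritParams retrograde_clint
#' @return Metabolic blood clearance, L/h.
#' @export
forward_metabolic_cl <- function(per_enzyme_clu_int, fu_b, system,
                                 tissue_scalars = NULL) {
  pools <- scaled_pools(system, tissue_scalars)
  enz <- names(per_enzyme_clu_int)
  c_e <- unlist(per_enzyme_clu_int)
  clu_h <- sum(c_e * pools$liver[enz]) * UL_MIN_TO_L_H
  clu_r <- sum(c_e * pools$kidney[enz]) * UL_MIN_TO_L_H
  well_stirred_cl(clu_h, fu_b, system$q_hepatic) +
    well_stirred_cl(clu_r, fu_b, system$q_kidney)
}

#' @export
print.pbpk_clearances <- function(x, ...) {
  cat("Derived clearances (retrograde, well-stirred liver + kidney)\n")
  cat(sprintf("  fu,blood             : %.4f\n", x$fu_blood))
  cat(sprintf("  CLu,int hepatic      : %.1f L/h\n", x$clu_int_hepatic))
  if (x$clu_int_renal > 0)
    cat(sprintf("  CLu,int renal        : %.2f L/h\n", x$clu_int_renal))
  cat(sprintf("  CL hepatic (blood)   : %.2f L/h   (FH = %.3f)\n",
              x$cl_hepatic_blood, x$fh))
  cat("  per-isoform CLu,int (µL/min/pmol):\n")
  for (e in names(x$per_enzyme_clu_int))
    cat(sprintf("    %-8s %.4g\n", e, x$per_enzyme_clu_int[[e]]))
  invisible(x)
}
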