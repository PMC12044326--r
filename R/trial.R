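# Virtual DDI trial orchestration: simulate both arms in the same virtual
# population (within-subject contrast), apply NCA, summarize GMRs with 90% CI.

#' Run a virtual DDI study
#'
#' Simulates the victim drug in every subject of a virtual population with
#' and (when the design has a perpetrator) without co-administration - the
#' same individuals in both arms, as in a crossover - applies
#' non-compartmental analysis to each victim profile and reports geometric
#' mean exposures per arm and within-subject geometric mean ratios with 90%
#' confidence intervals.
#'
#' @param design A [study_design()].
#' @param compounds Optional named list of `pbpk_compound` objects resolving
#'   the design's compound references (defaults to the packaged library).
#' @param system Reference system parameters.
#' @param cv_spec Between-subject CV overrides, see [sample_population()].
#' @param seed Population seed (both arms share the population).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `ddi_study`: `metrics` (per subject and arm),
#'   `geomean` (per-arm geometric mean Cmax/AUC), `gmr_cmax`, `gmr_auc`
#'   (each `gmr`, `lo`, `hi`, `n`), and the design.
#' @export
run_ddi_study <- function(design, compounds = NULL, system = default_system(),
                          cv_spec = NULL, seed = 1L, rtol = 1e-8, atol = 1e-10) {
  problems <- validate_study(design, compounds)
  if (length(problems)) {
    stop("study design not runnable:\n  - ", paste(problems, collapse = "\n  - "))
  }
  resolve <- function(ref) {
    if (inherits(ref, "pbpk_compound")) return(ref)
    if (!is.null(compounds) && ref %in% names(compounds)) return(compounds[[ref]])
    builtin_compound(ref)
  }
  victim <- resolve(design$victim$compound)
  perp <- if (!is.null(design$perpetrator)) resolve(design$perpetrator$compound)
  pop <- sample_population(design, system, cv_spec, seed)

  ref_design <- design
  ref_design$perpetrator <- NULL

  one_arm <- function(ind, with_perp) {
    d <- if (with_perp) design else ref_design
    sim <- simulate_pk(victim, d, ind,
                       perpetrator = if (with_perp) perp else NULL,
                       rtol = rtol, atol = atol, ref_system = system)
    m <- nca(sim$victim, subject = ind$id)
    data.frame(subject = ind$id, arm = if (with_perp) "test" else "reference",
               cmax = m$cmax, auc_0_t = m$auc_0_t, auc_0_inf = m$auc_0_inf,
               lambda_z = m$lambda_z)
  }

  res_ref <- do.call(rbind, lapply(pop, one_arm, with_perp = FALSE))
  res_test <- if (!is.null(perp)) {
    do.call(rbind, lapply(pop, one_arm, with_perp = TRUE))
  }
  metrics <- rbind(res_ref, res_test)

  gm_tab <- stats::aggregate(cbind(cmax, auc_0_inf) ~ arm, data = metrics,
                             FUN = geomean)
  out <- list(design = design, metrics = metrics, geomean = gm_tab,
              n = length(pop), seed = seed)
  if (!is.null(perp)) {
    out$gmr_cmax <- gmr(res_test$cmax, res_ref$cmax)
    out$gmr_auc <- gmr(res_test$auc_0_inf, res_ref$auc_0_inf)
  }
  structure(out, class = "ddi_study")
}

#' @export
print.ddi_study <- function(x, ...) {
  v <- x$design$victim
  vn <- if (is.character(v$compound)) v$compound else v$compound$name
  cat(sprintf("Virtual DDI study (n = %d): victim %s %g mg\n", x$n, vn, v$dose))
  p <- x$design$perpetrator
  if (!is.null(p)) {
    pn <- if (is.character(p$compound)) p$compound else p$compound$name
    cat(sprintf("  perpetrator %s %g mg x%d q%gh\n", pn, p$dose, p$n_doses,
                p$interval))
  }
  cat("  geometric means per arm:\n")
  print(x$geomean, row.names = FALSE)
  if (!is.null(x$gmr_auc)) {
    cat(sprintf("  Cmax GMR %.3g (90%% CI %.3g-%.3g)\n",
                x$gmr_cmax["gmr"], x$gmr_cmax["lo"], x$gmr_cmax["hi"]))
    cat(sprintf("  AUC0-inf GMR %.3g (90%% CI %.3g-%.3g)\n",
                x$gmr_auc["gmr"], x$gmr_auc["lo"], x$gmr_auc["hi"]))
  }
  invisible(x)
}

#' @export
summary.ddi_study <- function(object, ...) {
  print(object)
  invisible(object$metrics)
}
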