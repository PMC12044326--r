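# Study designs: victim/perpetrator regimens, population description and the
# report-based design validator.

#' Construct a DDI study design
#'
#' @param victim List: `compound` (name resolvable by [builtin_compound()] or
#'   a `pbpk_compound`), `dose` (mg), `route` (`"oral"` or `"iv"`),
#'   `n_doses` (default 1) and `interval` (h, default 24).
#' @param perpetrator Optional list with the same regimen fields plus
#'   `victim_dose_day`: the perpetrator dosing day (1-based) on which the
#'   victim dose is co-administered; perpetrator dosing starts at time 0 and
#'   continues through the victim sampling window.
#' @param population List: `n`, `age_range` (years, length 2), `prop_female`.
#' @param followup Sampling duration after the victim dose, h.
#' @param ki_scale Optional named vector of fold-reductions applied to the
#'   perpetrator's unbound inhibition constants (sensitivity scans).
#' @param induction_groups Character vector of induction-block group labels to
#'   enable in addition to always-on (ungrouped) blocks; e.g. a perpetrator
#'   file may carry a hypothesis block under group `"ugt"`.
#' @param outputs Metrics to report (informational).
#' @return Object of class `ddi_design`.
#' @export
study_design <- function(victim, perpetrator = NULL,
                         population = list(n = 100, age_range = c(20, 50),
                                           prop_female = 0.5),
                         followup = 168, ki_scale = NULL,
                         induction_groups = character(),
                         outputs = c("cmax", "auc_0_inf")) {
  victim$n_doses <- victim$n_doses %||% 1L
  victim$interval <- victim$interval %||% 24
  victim$route <- victim$route %||% "oral"
  if (!is.null(perpetrator)) {
    perpetrator$n_doses <- perpetrator$n_doses %||% 1L
    perpetrator$interval <- perpetrator$interval %||% 24
    perpetrator$route <- perpetrator$route %||% "oral"
    perpetrator$victim_dose_day <- perpetrator$victim_dose_day %||% 1L
  }
  structure(list(victim = victim, perpetrator = perpetrator,
                 population = population, followup = followup,
                 ki_scale = ki_scale, induction_groups = induction_groups,
                 outputs = outputs),
            class = "ddi_design")
}

#' Validate a study design against available compound models
#'
#' Report-based validation: returns a character vector of problems; an empty
#' report means the design is runnable.
#'
#' @param design A [study_design()].
#' @param compounds Available models: a named list of `pbpk_compound` objects,
#'   or `NULL` to resolve against the packaged library.
#' @return Character vector of problem descriptions (length 0 if runnable).
#' @export
validate_study <- function(design, compounds = NULL) {
  report <- character()
  resolve <- function(ref) {
    if (inherits(ref, "pbpk_compound")) return(TRUE)
    if (is.character(ref)) {
      return(ref %in% names(compounds) || ref %in% compound_library())
    }
    FALSE
  }
  v <- design$victim
  if (is.null(v)) {
    report <- c(report, "no victim block")
  } else {
    if (!resolve(v$compound)) {
      report <- c(report, paste0("unresolved victim compound ref: ",
                                 if (is.character(v$compound)) v$compound else "<object>"))
    }
    if (is.null(v$dose) || v$dose <= 0) {
      report <- c(report, "victim dose must be > 0")
    }
    if (!is.null(v$route) && !v$route %in% c("oral", "iv")) {
      report <- c(report, paste0("unknown victim route: ", v$route))
    }
  }
  p <- design$perpetrator
  if (!is.null(p)) {
    if (!resolve(p$compound)) {
      report <- c(report, paste0("unresolved perpetrator compound ref: ",
                                 if (is.character(p$compound)) p$compound else "<object>"))
    }
    if (is.null(p$dose) || p$dose <= 0) {
      report <- c(report, "perpetrator dose must be > 0")
    }
    span_days <- ceiling(p$n_doses * p$interval / 24)
    if (p$victim_dose_day < 1 || p$victim_dose_day > span_days) {
      report <- c(report, sprintf(
        "victim-dose day %d outside perpetrator regimen span (%d day(s))",
        p$victim_dose_day, span_days))
    }
  }
  pop <- design$population
  if (is.null(pop$n) || pop$n < 1) report <- c(report, "population n must be >= 1")
  ar <- pop$age_range %||% c(20, 50)
  if (length(ar) != 2 || ar[1] > ar[2] || ar[1] < 0) {
    report <- c(report, "invalid age range")
  }
  pf <- pop$prop_female %||% 0.5
  if (pf < 0 || pf > 1) report <- c(report, "prop_female must lie in [0, 1]")
  report
}

#' @export
print.ddi_design <- function(x, ...) {
  v <- x$victim
  vn <- if (is.character(v$compound)) v$compound else v$compound$name
  cat(sprintf("DDI study design: %s %g mg %s x%d q%gh\n", vn, v$dose, v$route,
              v$n_doses, v$interval))
  p <- x$perpetrator
  if (!is.null(p)) {
    pn <- if (is.character(p$compound)) p$compound else p$compound$name
    cat(sprintf("  + %s %g mg x%d q%gh (victim dosed on perpetrator day %d)\n",
                pn, p$dose, p$n_doses, p$interval, p$victim_dose_day))
  }
  cat(sprintf("  population n=%d, age %g-%g, %g%% female; follow-up %g h\n",
              x$population$n, x$population$age_range[1], x$population$age_range[2],
              100 * (x$population$prop_female %||% 0.5), x$followup))
  invisible(x)
}
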