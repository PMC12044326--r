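# System (population physiology) parameters: defaults, validation, and
# per-individual scaling.

#' Default system (population physiology) parameters
#'
#' Reads the packaged system file describing the reference healthy adult:
#' organ weights and flows, microsomal scaling factors, per-enzyme tissue
#' abundances, enzyme turnover rates, default between-subject coefficients of
#' variation and the permeability calibrator scale. Per-value provenance is
#' documented in the file itself (`system.file("extdata/system/default_system.yaml",
#' package = "pbpkddi")`), which users may copy and edit.
#'
#' @param path Optional path to an alternative system file.
#' @return A validated list of class `pbpk_system`.
#' @export
#' @examples
#' sys <- default_system()
#' sys$q_hepatic
default_system <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "system", "default_system.yaml",
                        package = "pbpkddi")
  }
  stopifnot(file.exists(path))
  sys <- yaml::read_yaml(path)
  validate_system(sys)
}

#' Validate a system parameter list
#'
#' Checks positivity of all physiological scalars and that every enzyme in
#' the controlled vocabulary (transporters excepted) carries liver, intestine
#' and kidney abundance entries.
#'
#' @param sys A system parameter list.
#' @return The list, classed `pbpk_system`, invisibly usable downstream.
#' @export
validate_system <- function(sys) {
  num_fields <- c("body_weight_ref", "liver_weight", "liver_volume", "mppgl",
                  "kidney_weight", "mppgk", "q_hepatic", "q_kidney",
                  "q_villous", "enterocyte_volume", "si_radius", "si_transit",
                  "gfr")
  for (f in num_fields) {
    v <- sys[[f]]
    if (is.null(v) || !is.numeric(v) || v <= 0) {
      stop("system parameter '", f, "' missing or non-positive")
    }
  }
  for (e in metabolic_enzymes()) {
    ab <- sys$abundance[[e]]
    if (is.null(ab)) stop("system file lacks abundance block for enzyme ", e)
    for (tis in c("liver", "intestine", "kidney")) {
      v <- ab[[tis]]
      if (is.null(v) || !is.numeric(v) || v < 0) {
        stop("system abundance for ", e, " in ", tis, " missing or negative")
      }
    }
  }
  if (is.null(sys$kdeg$liver) || is.null(sys$kdeg$intestine) ||
      sys$kdeg$liver <= 0 || sys$kdeg$intestine <= 0) {
    stop("system kdeg (liver, intestine) must be positive")
  }
  structure(sys, class = "pbpk_system")
}

#' @export
print.pbpk_system <- function(x, ...) {
  cat("System parameters:", x$name %||% "(unnamed)", "\n")
  cat(sprintf("  reference weight %g kg; liver %g g (MPPGL %g mg/g); Q_H %g L/h\n",
              x$body_weight_ref, x$liver_weight, x$mppgl, x$q_hepatic))
  cat("  enzymes with nonzero liver abundance:",
      paste(names(Filter(function(a) a$liver > 0, x$abundance)), collapse = ", "),
      "\n")
  invisible(x)
}

# Scale the reference system to one individual's body weight: blood flows
# allometrically (exponent 0.75), organ sizes/volumes and intestinal enzyme
# pools linearly, per-mg abundances unchanged.
scale_system <- function(sys, weight) {
  s <- sys
  rel <- weight / sys$body_weight_ref
  fl <- rel^0.75
  for (f in c("q_hepatic", "q_kidney", "q_villous", "gfr")) s[[f]] <- sys[[f]] * fl
  for (f in c("liver_weight", "liver_volume", "kidney_weight",
              "enterocyte_volume")) s[[f]] <- sys[[f]] * rel
  for (e in names(s$abundance)) {
    s$abundance[[e]]$intestine <- sys$abundance[[e]]$intestine * rel
  }
  s$body_weight <- weight
  s
}
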