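# Compound model: the structured per-drug parameter set (physicochemistry,
# binding, absorption, minimal-PBPK distribution, per-isoform elimination,
# interaction and induction blocks), its validation, and YAML file I/O.
#
# Schema conventions: units are fixed by the schema (no in-file unit
# expressions); enzyme names come from the closed controlled vocabulary;
# unknown keys are rejected so typos cannot silently drop parameters.

.compound_keys <- list(
  top = c("name", "mw", "logp", "compound_class", "pka", "bp_ratio",
          "fu_plasma", "binding_protein", "absorption", "distribution",
          "elimination", "interaction", "induction", "provenance"),
  absorption = c("model", "papp_caco2", "peff_man", "ka", "fa", "fu_gut",
                 "qgut"),
  distribution = c("model", "vss", "kp_scalar", "k_in", "k_out", "v_sac",
                   "kp_liver"),
  elimination = c("cl_iv", "cl_renal", "fm", "clint", "mm", "tissue_scalars",
                  "gut_pool", "efflux", "cl_add"),
  interaction = "ki",
  induction = c("target", "ind_max", "ind_c50", "hill", "tissues", "group")
)

.check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
}

.need <- function(block, field, where) {
  v <- block[[field]]
  if (is.null(v)) stop("missing mandatory field '", field, "' in ", where,
                       call. = FALSE)
  v
}

#' Construct a compound model
#'
#' Assembles and validates the full per-drug parameter set used throughout
#' the package. Most users will call [load_compound()] on a compound file or
#' [builtin_compound()] for a packaged drug instead.
#'
#' @param name Compound name.
#' @param mw Molecular weight, g/mol.
#' @param bp_ratio Blood:plasma concentration ratio.
#' @param fu_plasma Fraction unbound in plasma (0, 1].
#' @param absorption List: `model` (`"first_order"`), and either measured
#'   Caco-2 permeability (`papp_caco2`, 1e-6 cm/s) or explicit `peff_man`
#'   (1e-4 cm/s) or direct `ka` (1/h) and `fa`; `fu_gut` (fraction) and
#'   `qgut` (L/h) for the Qgut first-pass model. Explicit `ka`/`fa` take
#'   precedence over prediction.
#' @param distribution List: `vss` (L/kg), `kp_scalar` (unitless multiplier on
#'   the distribution volume), and the single-adjusting-compartment terms
#'   `k_in`, `k_out` (1/h) and `v_sac` (L/kg); `k_in = k_out = 0` gives a
#'   one-compartment systemic model.
#' @param elimination List: optional `cl_iv` (L/h, observed systemic
#'   clearance, enables retrograde derivation), `cl_renal` (L/h), `fm` (named
#'   fractions of net metabolic clearance), `clint` (named linear intrinsic
#'   clearances, µL/min/pmol), `mm` (named lists `vmax` pmol/min/pmol, `km`
#'   µM), `tissue_scalars`, `gut_pool` (pmol, replaces the system intestinal
#'   pool for the named enzyme), `efflux` (list `transporter`, `cl` L/h
#'   intestinal efflux clearance) and `cl_add` (L/h additional linear systemic
#'   clearance not assigned to a modeled isoform).
#' @param interaction Optional list with `ki`: named map target ->
#'   `list(ki = µM total, fu_mic = fraction)`. The unbound constant
#'   `ki_u = ki * fu_mic` is always derived, never stored.
#' @param induction Optional list of blocks `list(target=, ind_max=,
#'   ind_c50= µM unbound, hill = 1, tissues = c("liver","intestine"),
#'   group = NULL)`; `group` labels toggleable hypothesis blocks.
#' @param logp,compound_class,pka,binding_protein Physicochemical descriptors
#'   (carried, not consumed by the solver).
#' @param provenance Free-text provenance notes.
#' @return Object of class `pbpk_compound`.
#' @export
pbpk_compound <- function(name, mw, bp_ratio, fu_plasma, absorption,
                          distribution, elimination, interaction = NULL,
                          induction = NULL, logp = NA_real_,
                          compound_class = "neutral", pka = NA_real_,
                          binding_protein = NA_character_, provenance = NULL) {
  x <- list(name = name, mw = mw, logp = logp, compound_class = compound_class,
            pka = pka, bp_ratio = bp_ratio, fu_plasma = fu_plasma,
            binding_protein = binding_protein, absorption = absorption,
            distribution = distribution, elimination = elimination,
            interaction = interaction, induction = induction,
            provenance = provenance)
  validate_compound(x)
}

#' Validate a compound model
#'
#' Enforces every schema invariant: positive molecular weight, fractions in
#' range, `fm` values summing to at most 1, Michaelis constants positive, an
#' enzyme appearing in at most one of the linear and Michaelis-Menten
#' clearance maps, all enzyme names drawn from [enzyme_vocabulary()], and no
#' unknown keys anywhere.
#'
#' @param x A compound model list.
#' @return The validated object, classed `pbpk_compound`.
#' @export
validate_compound <- function(x) {
  where <- paste0("compound '", x$name %||% "?", "'")
  .check_keys(x, .compound_keys$top, where)
  nm <- .need(x, "name", where)
  mw <- .need(x, "mw", where)
  if (!is.numeric(mw) || mw <= 0) stop("mw must be > 0 in ", where)
  fu <- .need(x, "fu_plasma", where)
  if (fu <= 0 || fu > 1) stop("fu_plasma must lie in (0, 1] in ", where)
  bp <- .need(x, "bp_ratio", where)
  if (bp <= 0) stop("bp_ratio must be > 0 in ", where)

  ab <- .need(x, "absorption", where)
  .check_keys(ab, .compound_keys$absorption, paste0(where, " $absorption"))
  has_papp <- !is.null(ab$papp_caco2)
  has_peff <- !is.null(ab$peff_man)
  has_kafa <- !is.null(ab$ka) && !is.null(ab$fa)
  if (!(has_papp || has_peff || has_kafa)) {
    stop("absorption block needs papp_caco2, peff_man, or explicit ka + fa in ",
         where)
  }
  if (!is.null(ab$fa) && (ab$fa <= 0 || ab$fa > 1)) {
    stop("fa must lie in (0, 1] in ", where)
  }
  if (is.null(ab$fu_gut) || ab$fu_gut <= 0 || ab$fu_gut > 1) {
    stop("absorption fu_gut must lie in (0, 1] in ", where)
  }
  if (is.null(ab$qgut) || ab$qgut <= 0) stop("absorption qgut must be > 0 in ", where)

  di <- .need(x, "distribution", where)
  .check_keys(di, .compound_keys$distribution, paste0(where, " $distribution"))
  if (is.null(di$vss) || di$vss <= 0) stop("distribution vss must be > 0 in ", where)
  di$kp_scalar <- di$kp_scalar %||% 1
  di$k_in <- di$k_in %||% 0
  di$k_out <- di$k_out %||% 0
  di$v_sac <- di$v_sac %||% 0
  if (di$k_in < 0 || di$k_out < 0 || di$v_sac < 0) {
    stop("distribution rate constants and v_sac must be nonnegative in ", where)
  }
  if ((di$k_in > 0) != (di$k_out > 0)) {
    stop("k_in and k_out must both be positive or both zero in ", where)
  }
  if (di$v_sac >= di$vss) stop("v_sac must be smaller than vss in ", where)
  x$distribution <- di

  el <- .need(x, "elimination", where)
  .check_keys(el, .compound_keys$elimination, paste0(where, " $elimination"))
  el$cl_renal <- el$cl_renal %||% 0
  if (el$cl_renal < 0) stop("cl_renal must be nonnegative in ", where)
  fm <- unlist(el$fm %||% list())
  if (length(fm)) {
    if (any(fm < 0)) stop("fm values must be nonnegative in ", where)
    if (sum(fm) > 1 + 1e-9) {
      stop("fm values sum to ", signif(sum(fm), 4), " > 1 in ", where)
    }
  }
  lin <- names(el$clint %||% list())
  mm <- names(el$mm %||% list())
  dup <- intersect(lin, mm)
  if (length(dup)) {
    stop("enzyme(s) in both linear and Michaelis-Menten maps: ",
         paste(dup, collapse = ", "), " in ", where)
  }
  for (e in mm) {
    b <- el$mm[[e]]
    if (is.null(b$vmax) || is.null(b$km) || b$km <= 0 || b$vmax < 0) {
      stop("mm block for ", e, " needs vmax >= 0 and km > 0 in ", where)
    }
  }
  for (e in lin) {
    if (el$clint[[e]] < 0) stop("linear clint for ", e, " negative in ", where)
  }
  all_enz <- unique(c(names(fm), lin, mm, names(el$tissue_scalars %||% list()),
                      names(el$gut_pool %||% list())))
  bad <- setdiff(all_enz, metabolic_enzymes())
  if (length(bad)) {
    stop("unknown enzyme name(s): ", paste(bad, collapse = ", "), " in ", where)
  }
  if (!is.null(el$efflux)) {
    if (is.null(el$efflux$cl) || el$efflux$cl < 0) {
      stop("efflux block needs nonnegative cl in ", where)
    }
    el$efflux$transporter <- el$efflux$transporter %||% "P-gp"
    if (!el$efflux$transporter %in% enzyme_vocabulary()) {
      stop("unknown efflux transporter in ", where)
    }
  }
  el$cl_add <- el$cl_add %||% 0
  x$elimination <- el

  if (!is.null(x$interaction)) {
    .check_keys(x$interaction, "ki", paste0(where, " $interaction"))
    for (tg in names(x$interaction$ki)) {
      if (!tg %in% enzyme_vocabulary()) {
        stop("unknown interaction target '", tg, "' in ", where)
      }
      b <- x$interaction$ki[[tg]]
      if (is.null(b$ki) || b$ki <= 0) stop("ki for ", tg, " must be > 0 in ", where)
      b$fu_mic <- b$fu_mic %||% 1
      if (b$fu_mic <= 0 || b$fu_mic > 1) {
        stop("fu_mic for ", tg, " must lie in (0, 1] in ", where)
      }
      if (!is.null(b$ki_u)) stop("ki_u is derived, never stored (", where, ")")
      x$interaction$ki[[tg]] <- b
    }
  }
  if (!is.null(x$induction)) {
    for (i in seq_along(x$induction)) {
      b <- x$induction[[i]]
      .check_keys(b, .compound_keys$induction,
                  paste0(where, " $induction[", i, "]"))
      if (!(b$target %in% enzyme_vocabulary())) {
        stop("unknown induction target '", b$target, "' in ", where)
      }
      if (is.null(b$ind_max) || b$ind_max < 0) {
        stop("ind_max must be >= 0 in ", where)
      }
      if (is.null(b$ind_c50) || b$ind_c50 <= 0) {
        stop("ind_c50 must be > 0 in ", where)
      }
      b$hill <- b$hill %||% 1
      b$tissues <- b$tissues %||% c("liver", "intestine")
      x$induction[[i]] <- b
    }
  }
  structure(x, class = "pbpk_compound")
}

#' Load a compound model from file
#'
#' Reads a YAML compound file, validates every schema invariant and returns
#' the compound model. Units are fixed by the schema; see [pbpk_compound()].
#'
#' @param path Path to a compound YAML file.
#' @return A `pbpk_compound` object.
#' @export
load_compound <- function(path) {
  stopifnot(file.exists(path))
  x <- yaml::read_yaml(path)
  validate_compound(x)
}

#' Write a compound model to file
#'
#' Serializes losslessly (17 significant digits) so that a save/load round
#' trip reproduces every numeric field exactly.
#'
#' @param compound A `pbpk_compound` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound <- function(compound, path) {
  stopifnot(inherits(compound, "pbpk_compound"))
  yaml::write_yaml(unclass(compound), path, precision = 17)
  invisible(path)
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat("Compound:", x$name, sprintf("(MW %.2f g/mol)\n", x$mw))
  cat(sprintf("  fu,p %.4g  B:P %.4g  class %s\n", x$fu_plasma, x$bp_ratio,
              x$compound_class))
  ab <- x$absorption
  cat(sprintf("  absorption: ka %s 1/h, fa %s, Qgut %g L/h\n",
              format(ab$ka %||% NA), format(ab$fa %||% NA), ab$qgut))
  di <- x$distribution
  cat(sprintf("  distribution: Vss %g L/kg (Kp scalar %g)", di$vss, di$kp_scalar))
  if (di$k_in > 0) cat(sprintf(", SAC k_in %g k_out %g V_sac %g L/kg",
                               di$k_in, di$k_out, di$v_sac))
  cat("\n")
  el <- x$elimination
  if (!is.null(el$cl_iv)) cat(sprintf("  CL_iv %g L/h, ", el$cl_iv))
  cat(sprintf("  CL_renal %g L/h\n", el$cl_renal))
  if (length(el$fm)) {
    cat("  fm:", paste(sprintf("%s %.3g", names(el$fm), unlist(el$fm)),
                       collapse = ", "), "\n")
  }
  if (!is.null(x$interaction)) {
    cat("  inhibits:", paste(names(x$interaction$ki), collapse = ", "), "\n")
  }
  if (!is.null(x$induction)) {
    cat("  induces:", paste(vapply(x$induction, `[[`, "", "target"),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# Unbound inhibition constant for one target, µM; NULL if the compound does
# not inhibit it.
ki_unbound <- function(compound, target) {
  b <- compound$interaction$ki[[target]]
  if (is.null(b)) return(NULL)
  b$ki * (b$fu_mic %||% 1)
}
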