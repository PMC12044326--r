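# Controlled vocabulary and unit conversion constants shared across the package.

#' Enzyme and transporter vocabulary
#'
#' The package works with a closed controlled vocabulary of drug-metabolizing
#' enzymes and transporters. Every enzyme named in a compound file must carry
#' tissue abundances in the system (population) file, so unknown names are
#' rejected rather than silently ignored. `"UserUGT1"` is a user-defined
#' intestinal UDP-glucuronosyltransferase: a first-class enzyme whose only
#' nonzero tissue scalar is intestinal, used to represent gut glucuronidation
#' that cannot be attributed to a characterized isoform.
#'
#' @return Character vector of recognized enzyme/transporter names.
#' @export
#' @examples
#' enzyme_vocabulary()
enzyme_vocabulary <- function() {
  c("CYP1A2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4",
    "UGT1A1", "UGT1A9", "UGT2B4", "UserUGT1", "P-gp")
}

# Enzymes that can carry metabolic clearance (transporters excluded).
metabolic_enzymes <- function() setdiff(enzyme_vocabulary(), "P-gp")

# Tissues in which enzyme activity is modeled.
enzyme_tissues <- function() c("liver", "intestine", "kidney")

# µL/min/pmol * pmol -> L/h  (1e-6 L/µL * 60 min/h)
UL_MIN_TO_L_H <- 60e-6

# mg/L -> µM given molecular weight in g/mol: conc_uM = conc_mgL * 1000 / mw
mgL_to_uM <- function(conc_mgL, mw) conc_mgL * 1000 / mw

uM_to_mgL <- function(conc_uM, mw) conc_uM * mw / 1000

`%||%` <- function(a, b) if (is.null(a)) b else a
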