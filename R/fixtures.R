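# Packaged compound library and synthetic-profile generators. Every library
# entry is a plain-text YAML compound file under extdata/compounds with
# in-file provenance notes distinguishing published model inputs,
# literature-sourced defaults and calibrated quantities.

.fixture_cache <- new.env(parent = emptyenv())

#' List the packaged compound library
#'
#' @return Character vector of compound names available to
#'   [builtin_compound()].
#' @export
compound_library <- function() {
  dir <- system.file("extdata", "compounds", package = "pbpkddi")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Load a packaged compound model
#'
#' @param name Library compound name (see [compound_library()]).
#' @return A validated `pbpk_compound`.
#' @export
#' @examples
#' soti <- builtin_compound("soticlestat")
#' soti$fu_plasma
builtin_compound <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  path <- system.file("extdata", "compounds", paste0(name, ".yaml"),
                      package = "pbpkddi")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown library compound '", name, "'; available: ",
         paste(compound_library(), collapse = ", "))
  }
  cmp <- load_compound(path)
  .fixture_cache[[name]] <- cmp
  cmp
}

#' Benchmark a perpetrator fixture against a published interaction window
#'
#' Runs the named perpetrator against a substrate in the dynamic engine and
#' reports the simulated AUC ratio against an acceptance window (for example
#' the published clinical span of potent-azole/midazolam interactions).
#' Report-based: fixture files are only ever changed manually.
#'
#' @param name Perpetrator library name.
#' @param substrate Substrate library name (default `"midazolam"`).
#' @param substrate_dose,perp_dose,perp_interval,perp_n Regimen, mg and h.
#' @param window Numeric length-2 acceptance window for the AUC ratio.
#' @param n Number of virtual subjects (small deterministic check by default).
#' @param seed Population seed.
#' @return List with `auc_ratio`, `window`, `pass`.
#' @export
calibrate_perpetrator <- function(name, substrate = "midazolam",
                                  substrate_dose = 5, perp_dose = 200,
                                  perp_interval = 24, perp_n = 14,
                                  window = c(NA, NA), n = 1, seed = 1) {
  des <- study_design(
    victim = list(compound = substrate, dose = substrate_dose),
    perpetrator = list(compound = name, dose = perp_dose,
                       interval = perp_interval, n_doses = perp_n,
                       victim_dose_day = ceiling(perp_n * perp_interval / 24)),
    population = list(n = n, age_range = c(20, 50), prop_female = 0.5),
    followup = 96)
  res <- run_ddi_study(des, seed = seed)
  gm <- res$gmr_auc["gmr"]
  list(auc_ratio = unname(gm), window = window,
       pass = if (all(is.na(window))) NA else
         unname(gm >= window[1] & gm <= window[2]))
}

#' Synthetic concentration profile with known analytic truth
#'
#' Generates a sum-of-exponentials concentration-time profile (optionally
#' with multiplicative lognormal noise) together with its closed-form AUC,
#' Cmax and terminal slope, for testing non-compartmental analysis.
#'
#' @param coefs Numeric vector of coefficients (ng/mL).
#' @param rates Numeric vector of first-order rates (1/h), same length;
#'   positive terms decay, use a negative coefficient with a larger rate for
#'   an absorption phase.
#' @param times Sampling times, h.
#' @param cv Multiplicative lognormal noise CV (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @return List of class `synth_profile`: `time`, `conc`, and `truth` with
#'   `auc_0_inf`, `auc_0_t`, `cmax`, `tmax`, `lambda_z`.
#' @export
synth_profile <- function(coefs, rates, times = seq(0, 48, by = 1), cv = 0,
                          seed = 1) {
  stopifnot(length(coefs) == length(rates), all(rates > 0), all(times >= 0))
  clean <- rowSums(vapply(seq_along(coefs),
                          function(i) coefs[i] * exp(-rates[i] * times),
                          numeric(length(times))))
  grid <- seq(0, max(times), length.out = 4096)
  cgrid <- rowSums(vapply(seq_along(coefs),
                          function(i) coefs[i] * exp(-rates[i] * grid),
                          numeric(length(grid))))
  auc_inf <- sum(coefs / rates)
  auc_t <- auc_inf - sum(coefs / rates * exp(-rates * max(times)))
  conc <- clean
  if (cv > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    conc <- clean * exp(stats::rnorm(length(clean), 0, sqrt(log(1 + cv^2))))
  }
  structure(list(
    time = times, conc = conc,
    truth = list(auc_0_inf = auc_inf, auc_0_t = auc_t,
                 cmax = max(cgrid), tmax = grid[which.max(cgrid)],
                 lambda_z = min(rates))
  ), class = "synth_profile")
}
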