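# Shared design builders and a tiny deterministic individual for unit tests.

small_pop <- function(n = 2) list(n = n, age_range = c(20, 50), prop_female = 0.5)

victim_ddi_design <- function(perp, dose, n = 2, interval = 24,
                              groups = character(), followup = 96) {
  study_design(
    victim = list(compound = "soticlestat", dose = 300),
    perpetrator = list(compound = perp, dose = dose, interval = interval,
                       n_doses = ceiling((14 * 24 + followup) / interval) + 1,
                       victim_dose_day = 15),
    population = small_pop(n), followup = followup,
    induction_groups = groups)
}

perp_ddi_design <- function(substrate, dose, n = 2, followup = 72) {
  study_design(
    victim = list(compound = substrate, dose = dose),
    perpetrator = list(compound = "soticlestat", dose = 300, interval = 12,
                       n_doses = ceiling((7 * 24 + followup) / 12) + 1,
                       victim_dose_day = 8),
    population = small_pop(n), followup = followup)
}

# A compound with purely linear hepatic clearance and effectively transparent
# gut/liver transit, for closed-form comparisons.
linear_test_compound <- function(clint = 0.5, vss = 0.5, ka = 1.0) {
  pbpk_compound(
    name = "linear-test", mw = 300, bp_ratio = 1, fu_plasma = 0.1,
    absorption = list(model = "first_order", ka = ka, fa = 1, fu_gut = 1,
                      qgut = 1e5),
    distribution = list(model = "minimal_pbpk", vss = vss, kp_scalar = 1),
    elimination = list(cl_renal = 0, clint = list(CYP3A4 = clint)))
}

fast_transit_individual <- function() {
  ind <- mean_individual()
  # shrink transit compartments so the topology collapses to one compartment
  ind$system$q_hepatic <- 1e5
  ind$system$q_kidney <- 1e5
  ind$system$liver_volume <- 1e-4
  ind$system$enterocyte_volume <- 1e-5
  ind
}
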