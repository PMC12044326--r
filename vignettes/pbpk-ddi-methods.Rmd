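---
title: "Methods: minimal-PBPK simulation of drug-drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimal-PBPK simulation of drug-drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpkddi)
```

## The problem

Soticlestat is a cholesterol 24-hydroxylase inhibitor in development for
developmental and epileptic encephalopathies, populations in which
polypharmacy is the rule. Its clearance is dominated by glucuronidation
(UGT2B4 with a smaller UGT1A9 share) with a minor CYP3A4 component, and in
vitro it weakly inhibits CYP2C8, CYP2C9, CYP2C19, CYP3A4 and P-glycoprotein.
`pbpkddi` implements an open, testable mechanistic framework for asking the
two regulatory questions this profile raises: how much do CYP3A inhibitors
and inducers change soticlestat exposure (victim liability), and how much
does multiple-dose soticlestat change the exposure of sensitive CYP2C8,
CYP2C9, CYP2C19, CYP3A4 and P-gp index substrates (perpetrator liability) —
each expressed as a geometric mean ratio (GMR) of AUC and Cmax in a virtual
crossover trial.

## The model

### Topology

Each drug is described by a minimal physiologically based model:

* **gut lumen** — receives oral doses; first-order transfer `ka` into the
  enterocyte, with a parallel loss channel sized so that the net fraction
  reaching the enterocyte is `fa`;
* **enterocyte** — washed out into the portal inflow at the compound's
  hybrid `Qgut` flow; site of intestinal metabolism (and of P-gp efflux back
  to the lumen for transporter substrates), evaluated at the unbound
  enterocyte concentration, so saturable gut metabolism and gut DDIs emerge
  dynamically;
* **liver** — an explicit well-stirred compartment. The minimal model is
  usually drawn without one, but local competitive inhibition and
  Michaelis-Menten kinetics need a local unbound concentration to act on;
  the explicit liver is the smallest extension that provides it, and at
  steady state it reduces exactly to the well-stirred organ model;
* **systemic compartment** with renal excretion (`CL_R`, treated as purely
  excretory), a lumped well-stirred kidney metabolic clearance (the renal
  UGTs), and a **single adjusting compartment** (SAC; `k_in`, `k_out`,
  `V_SAC`) giving multi-phasic disposition.

The distribution volume consistent with the reported `Vss` is split between
the systemic compartment and the SAC through the `k_in/k_out` equilibrium
(`V_sys = Vss / (1 + k_in/k_out)`); the reported `Kp` scalar is applied as a
uniform multiplier on that volume, isolated in one place. Concentrations are
tracked as plasma (reported in ng/mL), converted to blood at organ inlets
through the blood:plasma ratio, and to unbound via `fu/B:P`.

### Clearance parameterization

Per-isoform kinetics are carried per pmol of enzyme (µL/min/pmol), scaled to
organ clearances through tissue pools: liver abundance (pmol/mg) × MPPGL ×
liver weight, intestinal pools in pmol, kidney abundance × MPPGK × kidney
weight. Enzymes may be linear (`CLint`) or Michaelis-Menten (`Vmax`, `Km`,
referenced to the local unbound concentration in µM); the UGTs here are
saturable with `Km` 5 µM, which is what produces the greater-than-dose-
proportional exposure the package's dose-superposition tests assert.

When a compound file carries an observed systemic clearance, the package
derives per-isoform values retrogradely: the metabolic blood clearance
(`CL_IV − CL_R`, converted through B:P) is apportioned across isoforms in
proportion to `fm` and scaled so that the forward well-stirred liver +
kidney clearances reproduce it exactly (a solved one-dimensional root,
verified to 1e-8 by a round-trip test). Because UGT1A9 and UGT2B4 are also
renal, the kidney participates in this inversion; `CL_R` itself stays
purely excretory.

### Absorption

`Peff` is calibrated from Caco-2 permeability by a log-log regression
through a low/high anchor pair (atenolol, propranolol) whose reference-scale
values ship in the system file; `ka = 2·Peff/R_SI` and
`fa = 1 − (1 + ka·T_SI/7)^−7` (a seven-compartment transit closed form).
With the packaged geometry (R 1.65 cm, T 3.32 h) the reference compound's
measured Papp of 23.4×10⁻⁶ cm/s maps to Peff 3.76×10⁻⁴ cm/s, ka 1.64/h and
fa 0.98; the compound file's explicit ka 1.2/h (the reported manual
adjustment to the observed tmax) takes precedence, as explicit values always
do. Gut first-pass availability follows the Qgut model,
`FG = Qgut/(Qgut + fu_gut·CLu_int,gut)`, dynamically rather than as a fixed
fraction.

### Interactions

Competitive inhibition multiplies an enzyme's intrinsic clearance by
`1/(1 + Cu/Ki,u)` with `Ki,u = Ki × fu_mic` always derived, never stored.
Induction is a turnover model per enzyme × tissue:
`dE/dt = kdeg·(E0·(1 + IndMax·Cu^h/(IndC50^h + Cu^h)) − E)`, so a 14-day
inducer lead-in approaches its steady state on the enzyme's own half-life
(liver ≈ 36 h, gut ≈ 23 h here). Victim and perpetrator are integrated
simultaneously; inhibition follows the perpetrator's local concentrations
instant by instant, with no constant-[I] shortcut.

**Local drivers.** Hepatic enzymes see the unbound liver outflow
concentration and kidney enzymes the unbound systemic blood concentration.
For gut enzymes (and intestinal efflux) the driver is the absorbed flux
diluted into total hepatic inflow blood, `Qgut·C_ent/Q_H` — a flux-over-flow
convention from the same family as the static gut interaction term. The raw
enterocyte concentration was rejected deliberately: under first-order
absorption the Qgut washout of a 300 mg dose puts transient enterocyte
concentrations in the hundreds of µM, which would predict near-complete gut
CYP3A4 inhibition by any co-dosed compound and is inconsistent with the weak
perpetrator interactions this class of model is known to produce. The
convention was fixed once, against the midazolam interaction pair (baseline
GMR and the 10-fold Ki,u sensitivity), before the other perpetrator studies
were run, and is shared by every study the package simulates.

## Virtual populations and trial statistics

`sample_population()` draws demographics (sex split honoured exactly, age
uniform in range, weight lognormal by sex), scales flows allometrically
(exponent 0.75) and organ sizes linearly, and applies lognormal
between-subject variability that preserves nominal values as geometric
means. The source literature for this model family does not print its
population CVs; the package defaults (abundances 30%, flows 15%, organ sizes
15%, MPPGL 25%, Vss 20%, ka 30%) are stated in the system file and
propagate into the GMR confidence intervals. Abundance variability is stored
as multiplicative factors so compound-level pool overrides inherit the
subject's draw.

DDI trials are within-subject: the same virtual individuals are simulated
with and without the perpetrator, mirroring a crossover and producing the
tight 90% CIs characteristic of paired designs. Exposure metrics come from
non-compartmental analysis (linear-up/log-down trapezoid; terminal slope by
the best adjusted-R² log-linear fit over the last 3–8 points excluding Cmax
— a deterministic rule chosen because the source is silent and this is
standard NCA practice); `gmr()` is the exact paired log-scale t procedure.

## Calibration policy

Three quantities in the shipped files are calibrations, each fitted once
against a stated anchor and then frozen; everything else is either the
published compound input set (the soticlestat file reproduces it
field-for-field) or literature-sourced with provenance notes in the file:

1. **UserUGT1 intestinal pool** (33,500 pmol at 70 kg) — the published model
   gives the user-defined intestinal UGT its kinetics and an intestinal
   scalar of 1 but no abundance, leaving oral bioavailability unidentified;
   the pool was fitted to the reported simulated 300 mg single-dose AUC.
2. **Liver UGT2B4/UGT1A9/CYP3A4 abundances** — chosen jointly (within
   quantitative-proteomics ranges) so the retrograde derivation returns the
   reported per-isoform intrinsic clearances (4.069/0.556/0.161
   µL/min/pmol).
3. **Perpetrator potencies** — the proprietary perpetrator files are not
   reproducible, so the open fixtures are benchmarked against public
   clinical anchors: itraconazole's net CYP3A4 Ki,u against the
   itraconazole–midazolam AUC-ratio window (5.47–10.77), rifampin's CYP3A4
   Emax against its midazolam interaction, and the rifampin UGT hypothesis
   blocks (UGT1A1 parameters applied to UGT1A9/UGT2B4/UserUGT1, toggleable
   via `induction_groups = "ugt"`) against the published UGT-extended victim
   simulation, since the borrowed UGT1A1 values themselves are never
   printed. The UGT-hypothesis comparison is therefore a calibrated, not
   parameter-free, reproduction.

## Numerical choices

`lsoda` (stiff-capable) with `rtol = 1e-8`, `atol = 1e-10`; dosing as
discrete add events; mass balance (all compartments plus cumulative
metabolized, excreted and unabsorbed mass against administered dose) is
checked on every run with a 0.1% gate, and a tolerance-halving test bounds
the AUC discretization error below 0.01%. The right-hand side is compiled C
for speed; an identical pure-R implementation remains available
(`engine = "R"`) and a test holds the two to 1e-8 agreement. States are
clamped at zero inside the RHS for rate evaluation; a final negativity check
rejects pathological solutions. When a co-administered perpetrator carries
no interaction mechanism the victim is integrated on its own time origin,
making the "inert perpetrator" study reproduce the victim-alone profile bit
for bit (asserted in tests). Degenerate inputs — zero dose, all-zero
profiles, non-monotone terminal phases — return zero profiles or flagged
NCA results rather than errors.

Problem sizes: the packaged studies use the study conditions of the source
analyses — 100 virtual subjects aged 20–50, 50% female, 14-day once-daily
perpetrator lead-ins for victim studies, 8 days of 300 mg twice-daily
dosing for perpetrator studies — and each two-arm n=100 study integrates in
seconds with the compiled engine.

## What the synthetic layer does and does not emulate

The generators cover exactly what the tests need: perpetrator
plasma/enterocyte exposure arises from simulating the perpetrator fixture
with the same engine (no imported profiles), and `synth_profile()` produces
sum-of-exponential concentration curves with closed-form AUC/Cmax truths,
optionally with multiplicative lognormal noise, as NCA oracles. None of this
emulates real bioanalytical data: no LLOQ censoring, no sampling-time
jitter, no residual error model, no enterohepatic recirculation (the
secondary absorption peak of the real compound is deliberately out of
scope), and the population is a single healthy-adult structure without
covariate physiology beyond weight and sex. Passing tests therefore
establish internal consistency with the stated model and its published
anchors, not fidelity to any individual clinical dataset.

## Known limitations

* The victim's rifampin interaction without UGT induction is expected to
  under-predict the observed clinical loss of exposure — that gap is the
  motivation for the toggleable UGT hypothesis block, and both variants are
  simulated.
* Perpetrator fixtures are deliberately minimal (one-compartment
  disposition, net potency): adequate for their role as exposure drivers,
  not as standalone models of those drugs; mefenamic acid in particular is
  included only as a no-effect regression.
* No time-dependent inhibition (the compound showed none in vitro), no
  OATP transport, no autoinduction of inducer fixtures (their steady-state
  clearances are used), and renal P-gp is inside lumped renal clearance, so
  digoxin interaction potential is expressed only through the gut-flux
  component.
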