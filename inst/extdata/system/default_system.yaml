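# Default virtual healthy-volunteer system (population) parameters.
# Reference individual: 70 kg adult. Flows scale with (WT/70)^0.75, organ
# sizes and volumes with (WT/70); per-mg microsomal abundances are weight
# invariant. Values are package defaults assembled from the open physiology
# literature (liver weight, MPPGL, hepatic/renal blood flow: Davies & Morris
# 1993; Barter et al. 2007; intestinal CYP3A4 pool: Paine et al. 1997;
# villous blood flow and Qgut geometry: Yang et al. 2007 "Prediction of
# intestinal first-pass drug metabolism"). UGT1A9, UGT2B4 and CYP3A4 liver
# abundances were calibrated once, jointly, so that the retrograde
# well-stirred derivation from the packaged reference compound's clinical
# disposition returns its reported per-isoform intrinsic clearances; they lie
# within reported quantitative-proteomics ranges. The kidney:liver abundance
# ratio for UGT1A9 (about 2:1 per mg microsomal protein) follows proteomic
# observations that UGT1A9 is strongly expressed in kidney; UGT2B4 kidney
# expression is minor. UserUGT1 is a user-defined intestinal UGT: its
# intestinal pool is a compound-calibration quantity and defaults to 0 here
# (compounds that use it carry their own pool size via the study layer).
name: healthy-adult-default
body_weight_ref: 70           # kg
liver_weight: 1650            # g
liver_volume: 1.571           # L (liver density 1.05 g/mL)
mppgl: 39.8                   # mg microsomal protein / g liver
kidney_weight: 310            # g (both kidneys)
mppgk: 12.8                   # mg microsomal protein / g kidney
q_hepatic: 86.4               # L/h total hepatic blood flow
q_kidney: 74.4                # L/h renal blood flow
q_villous: 18.0               # L/h villous mucosal blood flow
enterocyte_volume: 0.30       # L total enterocyte volume
si_radius: 1.65               # cm effective small-intestine radius
si_transit: 3.32              # h mean small-intestinal transit time
gfr: 6.5                      # L/h glomerular filtration rate
# Hepatic abundances pmol/mg microsomal protein; intestinal pools pmol total;
# kidney abundances pmol/mg kidney microsomal protein.
abundance:
  CYP1A2:   {liver: 52,   intestine: 0,     kidney: 0}
  CYP2B6:   {liver: 17,   intestine: 0,     kidney: 0}
  CYP2C8:   {liver: 24,   intestine: 700,   kidney: 0}
  CYP2C9:   {liver: 73,   intestine: 8400,  kidney: 0}
  CYP2C19:  {liver: 14,   intestine: 1600,  kidney: 0}
  CYP2D6:   {liver: 8,    intestine: 850,   kidney: 0}
  CYP3A4:   {liver: 125,  intestine: 70500, kidney: 0}
  UGT1A1:   {liver: 40,   intestine: 7000,  kidney: 0}
  UGT1A9:   {liver: 32,   intestine: 0,     kidney: 66}
  UGT2B4:   {liver: 39,   intestine: 0,     kidney: 6.5}
  UserUGT1: {liver: 0,    intestine: 0,     kidney: 0}
# First-order enzyme turnover rates (1/h). Liver CYP3A4 half-life about 36 h
# and intestinal about 23 h (Rowland Yeo et al. 2011); the same turnover is
# applied to the UGTs when an induction scenario requires one (the convention
# of borrowing the characterized hepatic UGT turnover).
kdeg:
  liver: 0.0193
  intestine: 0.030
# Default between-subject coefficients of variation (lognormal sampling,
# nominal value preserved as the geometric mean). The source publications for
# this model family do not print population CVs; these are package defaults.
cv:
  abundance: 0.30
  flows: 0.15
  organ_sizes: 0.15
  mppgl: 0.25
  vss: 0.20
  ka: 0.30
# Demographic weight model: lognormal by sex (geometric mean kg, CV).
demographics:
  weight_male: {gm: 78, cv: 0.16}
  weight_female: {gm: 64, cv: 0.18}
# Reference-scale effective jejunal permeability (1e-4 cm/s) for the Caco-2
# calibrator compounds. Atenolol is the measured human low-permeability
# anchor (Lennernas 1997); the propranolol value is the package's
# high-permeability scale anchor, set once so that the two-point log-log
# calibration reproduces the reference compound's reported predicted Peff
# from its measured Caco-2 Papp, and lying within the span of published
# Papp-to-Peff correlations for propranolol.
peff_calibrators:
  atenolol: {papp: 0.542, peff_ref: 0.20}
  propranolol: {papp: 27.8, peff_ref: 4.30}
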