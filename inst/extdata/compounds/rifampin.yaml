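# Rifampin (rifampicin): potent PXR-mediated inducer, index CYP3A4 inducer.
# Provenance: open literature disposition (fu ~0.15, Vss ~0.66 L/kg, oral
# clearance ~7 L/h at steady state); CYP3A4 Emax induction parameters in the
# range used by mechanistic DDI models (IndMax 10, unbound IndC50 0.32 µM).
# The UGT1A1 induction block represents PXR-mediated UGT up-regulation; the
# published magnitude of rifampin's UGT1A1 induction input is not available,
# so its Emax was calibrated once against the published UGT-extended victim
# simulation and frozen (maximal fold-induction 4, in the span of
# PXR-mediated UGT up-regulation reported in hepatocytes at saturation).
# The blocks under group "ugt" apply those same UGT1A1 parameters to UGT1A9,
# UGT2B4 and the user-defined intestinal UGT - a toggleable hypothesis
# (enable with study_design(induction_groups = "ugt")) representing UGT
# induction not present in the always-on set.
name: rifampin
mw: 822.9
logp: 2.7
compound_class: neutral
pka: 7.9
bp_ratio: 0.9
fu_plasma: 0.15
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.0
  fa: 0.95
  fu_gut: 1.0
  qgut: 8.0
distribution:
  model: minimal_pbpk
  vss: 0.66
  kp_scalar: 1.0
elimination:
  cl_add: 6.0
  cl_renal: 1.0
induction:
  - {target: CYP3A4, ind_max: 10.0, ind_c50: 0.32, hill: 1}
  - {target: UGT1A1, ind_max: 3.0, ind_c50: 1.0, hill: 1}
  - {target: UGT1A9, ind_max: 3.0, ind_c50: 1.0, hill: 1, group: ugt}
  - {target: UGT2B4, ind_max: 3.0, ind_c50: 1.0, hill: 1, group: ugt}
  - {target: UserUGT1, ind_max: 3.0, ind_c50: 1.0, hill: 1, group: ugt}
provenance: >
  Literature-sourced disposition and CYP3A4 induction parameters; UGT blocks
  borrow the UGT1A1 parameters (hepatocyte induction scale) as a toggleable
  hypothesis group.
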