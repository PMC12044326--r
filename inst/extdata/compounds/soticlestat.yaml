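# Soticlestat (TAK-935), cholesterol 24-hydroxylase inhibitor.
# Provenance: every value in this file except elimination.gut_pool.UserUGT1
# is the published final model input set for the compound (physicochemistry,
# binding, first-order absorption with Qgut first-pass, minimal-PBPK
# distribution with single adjusting compartment, per-isoform elimination
# with Michaelis-Menten UGT kinetics, and competitive interaction constants).
# The UserUGT1 intestinal pool (pmol, reference 70 kg adult) is the single
# calibration quantity of the open model: it was fitted once so that the
# simulated single-oral-dose 300 mg exposure in the reference virtual
# population matches the reported simulated geometric means, then frozen.
name: soticlestat
mw: 373.45
logp: 1.4
compound_class: monoprotic base
pka: 3.37
bp_ratio: 0.6866
fu_plasma: 0.066
binding_protein: AAG
absorption:
  model: first_order
  papp_caco2: 23.4
  ka: 1.2
  fa: 0.98
  fu_gut: 1.0
  qgut: 2.5
distribution:
  model: minimal_pbpk
  vss: 0.36
  kp_scalar: 1.091
  k_in: 0.219
  k_out: 0.216
  v_sac: 0.234
elimination:
  cl_iv: 28.7
  cl_renal: 0.22
  fm:
    UGT2B4: 0.8
    UGT1A9: 0.1
    CYP3A4: 0.1
  clint:
    CYP3A4: 0.161
  mm:
    UGT1A9: {vmax: 2.78, km: 5}
    UGT2B4: {vmax: 20.345, km: 5}
    UserUGT1: {vmax: 150, km: 5}
  tissue_scalars:
    UserUGT1: {liver: 0, intestine: 1, kidney: 0}
  gut_pool:
    UserUGT1: 33500
interaction:
  ki:
    CYP2C8: {ki: 14.5, fu_mic: 0.98}
    CYP2C9: {ki: 15.6, fu_mic: 0.88}
    CYP2C19: {ki: 9.5, fu_mic: 0.88}
    CYP3A4: {ki: 12.4, fu_mic: 0.94}
    P-gp: {ki: 80, fu_mic: 1.0}
provenance: >
  Published final compound model inputs; UserUGT1 intestinal pool calibrated
  once against the reported simulated 300 mg single-dose exposure and frozen.
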