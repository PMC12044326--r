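# Phenytoin: CYP3A4 inducer (antiseizure medication).
# Provenance: open literature - fu 0.1, Vss 0.64 L/kg, low-dose-range linear
# clearance ~2 L/h (saturable elimination not modeled at 300 mg QD);
# Emax induction parameters in the mechanistic-modeling range.
name: phenytoin
mw: 252.3
logp: 2.5
compound_class: monoprotic acid
pka: 8.3
bp_ratio: 0.9
fu_plasma: 0.1
binding_protein: albumin
absorption:
  model: first_order
  ka: 0.8
  fa: 0.9
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 0.64
  kp_scalar: 1.0
elimination:
  cl_add: 2.0
  cl_renal: 0.05
induction:
  - {target: CYP3A4, ind_max: 6.0, ind_c50: 5.0, hill: 1}
provenance: Literature-sourced disposition and induction parameters.
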