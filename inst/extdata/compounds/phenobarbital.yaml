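# Phenobarbital: CYP3A4 inducer (antiseizure medication).
# Provenance: open literature - fu 0.5, Vss 0.7 L/kg, very low clearance
# (~0.26 L/h, long half-life); Emax induction parameters in the
# mechanistic-modeling range.
name: phenobarbital
mw: 232.2
logp: 1.5
compound_class: monoprotic acid
pka: 7.3
bp_ratio: 0.86
fu_plasma: 0.5
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.0
  fa: 0.95
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 0.7
  kp_scalar: 1.0
elimination:
  cl_add: 0.2
  cl_renal: 0.06
induction:
  - {target: CYP3A4, ind_max: 3.0, ind_c50: 5.0, hill: 1}
provenance: Literature-sourced disposition and induction parameters.
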