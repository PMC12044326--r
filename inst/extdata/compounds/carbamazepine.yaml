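# Carbamazepine: moderate-to-strong CYP3A4 inducer (antiseizure medication).
# Provenance: open literature - fu 0.25, Vss ~1.2 L/kg, steady-state oral
# clearance ~4 L/h (autoinduced state used directly; autoinduction itself is
# not simulated); Emax induction parameters in the mechanistic-modeling range.
name: carbamazepine
mw: 236.3
logp: 2.5
compound_class: neutral
pka: 13.9
bp_ratio: 1.0
fu_plasma: 0.25
binding_protein: albumin
absorption:
  model: first_order
  ka: 0.6
  fa: 0.9
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 1.2
  kp_scalar: 1.0
elimination:
  cl_add: 4.0
  cl_renal: 0.1
induction:
  - {target: CYP3A4, ind_max: 6.0, ind_c50: 5.0, hill: 1}
provenance: Literature-sourced disposition and induction parameters.
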