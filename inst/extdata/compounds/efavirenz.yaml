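# Efavirenz: moderate CYP3A4 inducer.
# Provenance: open literature - very high protein binding (fu ~0.01),
# Vss ~3 L/kg, oral clearance ~9 L/h; induction parameters referenced to
# unbound concentration.
name: efavirenz
mw: 315.7
logp: 4.6
compound_class: neutral
pka: 10.2
bp_ratio: 0.74
fu_plasma: 0.01
binding_protein: albumin
absorption:
  model: first_order
  ka: 0.6
  fa: 0.6
  fu_gut: 1.0
  qgut: 8.0
distribution:
  model: minimal_pbpk
  vss: 3.0
  kp_scalar: 1.0
elimination:
  cl_add: 9.0
  cl_renal: 0.0
induction:
  - {target: CYP3A4, ind_max: 4.0, ind_c50: 0.2, hill: 1}
provenance: Literature-sourced disposition and induction parameters.
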