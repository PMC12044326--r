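# Cimetidine: weak competitive CYP3A4 inhibitor (index weak perpetrator).
# Provenance: open literature - fu 0.8, Vss ~1 L/kg, clearance ~30 L/h
# (two-thirds renal); weak micromolar CYP3A4 inhibition.
name: cimetidine
mw: 252.3
logp: 0.4
compound_class: monoprotic base
pka: 6.8
bp_ratio: 0.97
fu_plasma: 0.8
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.5
  fa: 0.75
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 1.0
  kp_scalar: 1.0
elimination:
  cl_add: 10.0
  cl_renal: 20.0
interaction:
  ki:
    CYP3A4: {ki: 40.0, fu_mic: 1.0}
provenance: Literature-sourced disposition and inhibition constant.
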