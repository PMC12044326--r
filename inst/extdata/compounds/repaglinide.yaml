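# Repaglinide: sensitive CYP2C8 index substrate (with a CYP3A4 component).
# Provenance: open literature - fu 0.015, B:P 0.62, Vss 0.4 L/kg, systemic
# clearance ~20 L/h, metabolism split roughly 60% CYP2C8 / 20% CYP3A4.
# Hepatic OATP1B1 uptake is not modeled; the systemic clearance carries the
# net disposition. High permeability gives a large Qgut (minimal intestinal
# first-pass extraction, consistent with its near-complete absorption).
name: repaglinide
mw: 452.6
logp: 3.6
compound_class: monoprotic acid
pka: 4.2
bp_ratio: 0.62
fu_plasma: 0.015
binding_protein: albumin
absorption:
  model: first_order
  ka: 2.0
  fa: 0.9
  fu_gut: 1.0
  qgut: 30.0
distribution:
  model: minimal_pbpk
  vss: 0.4
  kp_scalar: 1.0
elimination:
  cl_iv: 20.0
  cl_renal: 0.0
  fm:
    CYP2C8: 0.60
    CYP3A4: 0.20
provenance: Literature-sourced disposition; retrograde per-isoform split.
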