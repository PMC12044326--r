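# Omeprazole: sensitive CYP2C19 index substrate.
# Provenance: open literature - fu 0.05, Vss 0.3 L/kg, systemic clearance
# ~27 L/h, metabolism mainly CYP2C19 with a CYP3A4 sulfoxidation component.
name: omeprazole
mw: 345.4
logp: 2.2
compound_class: neutral
pka: 4.2
bp_ratio: 0.6
fu_plasma: 0.05
binding_protein: albumin
absorption:
  model: first_order
  ka: 2.0
  fa: 0.95
  fu_gut: 1.0
  qgut: 14.0
distribution:
  model: minimal_pbpk
  vss: 0.3
  kp_scalar: 1.0
elimination:
  cl_iv: 27.0
  cl_renal: 0.0
  fm:
    CYP2C19: 0.75
    CYP3A4: 0.20
provenance: Literature-sourced disposition; retrograde per-isoform split.
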