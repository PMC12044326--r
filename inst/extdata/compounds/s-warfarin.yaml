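# S-warfarin: sensitive CYP2C9 index substrate.
# Provenance: open literature - very low clearance (~0.27 L/h), fu 0.01,
# B:P 0.57, Vss 0.14 L/kg, fm,CYP2C9 about 0.91.
name: s-warfarin
mw: 308.3
logp: 2.7
compound_class: monoprotic acid
pka: 5.0
bp_ratio: 0.57
fu_plasma: 0.01
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.5
  fa: 0.98
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 0.14
  kp_scalar: 1.0
elimination:
  cl_iv: 0.27
  cl_renal: 0.0
  fm:
    CYP2C9: 0.91
provenance: Literature-sourced disposition; retrograde per-isoform split.
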