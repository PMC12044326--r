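# Midazolam: sensitive CYP3A4 index substrate.
# Provenance: open literature - fu 0.032, B:P 0.66, Vss ~1 L/kg, systemic
# clearance ~27 L/h with fm,CYP3A4 0.93; Qgut 16 L/h reproducing the
# well-established intestinal availability of about 0.57. Per-isoform
# intrinsic clearance is derived retrogradely from the systemic clearance.
name: midazolam
mw: 325.8
logp: 3.5
compound_class: monoprotic base
pka: 6.0
bp_ratio: 0.66
fu_plasma: 0.032
binding_protein: albumin
absorption:
  model: first_order
  ka: 3.0
  fa: 0.98
  fu_gut: 1.0
  qgut: 16.0
distribution:
  model: minimal_pbpk
  vss: 1.0
  kp_scalar: 1.0
elimination:
  cl_iv: 27.0
  cl_renal: 0.05
  fm:
    CYP3A4: 0.93
  cl_add: 0.0
provenance: Literature-sourced disposition; retrograde per-isoform split.
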