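# Fluconazole: moderate competitive CYP3A4 (and CYP2C9/2C19) inhibitor.
# Provenance: open literature - near-complete absorption, low protein binding
# (fu ~0.89), Vss ~0.7 L/kg, total clearance ~1.2 L/h of which ~70% renal;
# in vitro CYP3A4 Ki about 10 µM (negligible microsomal binding).
name: fluconazole
mw: 306.3
logp: 0.4
compound_class: neutral
pka: 2.0
bp_ratio: 1.0
fu_plasma: 0.89
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.5
  fa: 0.97
  fu_gut: 1.0
  qgut: 12.0
distribution:
  model: minimal_pbpk
  vss: 0.7
  kp_scalar: 1.0
elimination:
  cl_add: 0.36
  cl_renal: 0.84
interaction:
  ki:
    CYP3A4: {ki: 10.7, fu_mic: 1.0}
    CYP2C9: {ki: 30.0, fu_mic: 1.0}
    CYP2C19: {ki: 12.0, fu_mic: 1.0}
provenance: Literature-sourced disposition and in vitro inhibition constants.
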