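# Itraconazole: potent competitive CYP3A4 inhibitor (index perpetrator).
# Provenance: physicochemistry and disposition from the open clinical
# pharmacology literature (fu ~0.036, B:P 0.58, large Vss driving the long
# terminal half-life, oral clearance ~12 L/h); absorption first order.
# Inhibition potency: unbound Ki in the low-nanomolar range as used in
# mechanistic DDI modeling; the fixture as a whole is benchmarked against the
# published clinical itraconazole-midazolam AUC-ratio span (about 5.5-10.8)
# and frozen. Active metabolites are not modeled separately; the parent Ki
# carries the net potency.
name: itraconazole
mw: 705.6
logp: 5.7
compound_class: monoprotic base
pka: 3.7
bp_ratio: 0.58
fu_plasma: 0.036
binding_protein: albumin
absorption:
  model: first_order
  ka: 0.5
  fa: 0.9
  fu_gut: 1.0
  qgut: 3.0
distribution:
  model: minimal_pbpk
  vss: 7.0
  kp_scalar: 1.0
elimination:
  cl_add: 12.0
  cl_renal: 0.0
interaction:
  ki:
    CYP3A4: {ki: 0.015, fu_mic: 1.0}
provenance: >
  Literature-sourced disposition; net CYP3A4 potency benchmarked once against
  the clinical itraconazole-midazolam AUC-ratio window and frozen.
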