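# Mefenamic acid: potent UGT1A9 inhibitor. Included as a no-effect
# regression for the reference victim (whose UGT1A9 fraction metabolized is
# small and whose unbound exposure to mefenamic acid is low); no attempt is
# made to model its full PK fidelity.
# Provenance: open literature - fu ~0.01, Vss 1.06 L/kg, oral clearance
# ~5 L/h; sub-micromolar UGT1A9 inhibition.
name: mefenamic-acid
mw: 241.3
logp: 5.1
compound_class: monoprotic acid
pka: 4.2
bp_ratio: 0.6
fu_plasma: 0.01
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.2
  fa: 0.9
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 1.06
  kp_scalar: 1.0
elimination:
  cl_add: 5.0
  cl_renal: 0.03
interaction:
  ki:
    UGT1A9: {ki: 0.3, fu_mic: 1.0}
provenance: Literature-sourced disposition and inhibition constant.
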