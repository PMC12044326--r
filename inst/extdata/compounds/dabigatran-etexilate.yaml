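# Dabigatran etexilate: P-glycoprotein index substrate (prodrug; the
# profile simulated here is the absorbed moiety's systemic exposure on the
# etexilate dose scale). Oral availability is strongly P-gp-limited, which
# the large intestinal efflux clearance encodes.
# Provenance: open literature - low oral availability (~6-7%), Vss ~1 L/kg,
# high systemic clearance.
name: dabigatran-etexilate
mw: 627.7
logp: 3.8
compound_class: monoprotic base
pka: 6.7
bp_ratio: 0.71
fu_plasma: 0.65
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.0
  fa: 0.35
  fu_gut: 1.0
  qgut: 5.0
distribution:
  model: minimal_pbpk
  vss: 1.0
  kp_scalar: 1.0
elimination:
  cl_add: 30.0
  cl_renal: 9.0
  efflux: {transporter: P-gp, cl: 15.0}
provenance: Literature-sourced disposition; efflux encodes P-gp limitation.
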