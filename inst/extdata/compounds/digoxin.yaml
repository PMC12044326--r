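# Digoxin: P-glycoprotein index substrate, negligible metabolism.
# Provenance: open literature - fu 0.75, Vss ~7 L/kg, predominantly renal
# clearance (~7 L/h) with a small non-renal component. The intestinal efflux
# clearance represents the P-gp-limited gut-flux component only (renal P-gp
# secretion is inside the lumped renal clearance and is not an inhibition
# target here); it is sized so that complete P-gp blockade raises oral
# exposure by only a few percent, consistent with simulated weak gut-flux
# sensitivity for this compound.
name: digoxin
mw: 780.9
logp: 1.3
compound_class: neutral
pka: 7.2
bp_ratio: 1.0
fu_plasma: 0.75
binding_protein: albumin
absorption:
  model: first_order
  ka: 1.0
  fa: 0.85
  fu_gut: 1.0
  qgut: 10.0
distribution:
  model: minimal_pbpk
  vss: 7.0
  kp_scalar: 1.0
elimination:
  cl_add: 1.5
  cl_renal: 7.0
  efflux: {transporter: P-gp, cl: 2.0}
provenance: Literature-sourced disposition; gut efflux term sized as above.
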