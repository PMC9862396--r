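# Desmethyl tegoprazan (M1) compound parameters.  M1 is formed in the
# liver and gut wall by the CYP3A4/CYP2C19 reactions of the parent; it is
# eliminated by a lumped first-order total hepatic plasma clearance.
# Lipophilicity is tied to the parent value (jointly constrained during
# identification); solubility is a nominal placeholder because M1 is never
# dosed orally.
name: M1
molecular_weight: 373.40          # g/mol
logP: 1.75
fu_plasma: 0.01
solubility_mg_per_L: 1.0e-6       # 1 ng/mL, assumed
pka:
  - {value: 5.35, type: base}
total_hepatic_plasma_clearance_mL_min_kg: 0.140
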