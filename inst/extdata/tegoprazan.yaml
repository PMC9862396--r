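# Tegoprazan (parent) compound parameters: final model values.
# Clearance entries are first-order intrinsic clearances per pmol of
# recombinant enzyme; the in-vitro reference values and the intersystem
# extrapolation factors (ISEF 0.21 for CYP3A4, 0.25 for CYP2C19) used to
# seed parameter identification are kept alongside for provenance.
name: tegoprazan
molecular_weight: 387.38          # g/mol
logP: 1.75
fu_plasma: 0.087                  # fraction unbound in plasma
solubility_mg_per_L: 45.3
pka:
  - {value: 5.20, type: base}
  - {value: 12.0, type: acid}
specific_intestinal_permeability_cm_s: 1.16e-6
specific_organ_permeability_cm_s: 1.15e-4   # carried, inert under perfusion-limited distribution
renal_plasma_clearance_mL_min_kg: 0.297
reactions:
  - {enzyme: CYP3A4,  product: M1,    clint: 9.29e-3}   # uL/min/pmol
  - {enzyme: CYP3A4,  product: other, clint: 0.236}
  - {enzyme: CYP2C19, product: M1,    clint: 0.0921}
  - {enzyme: CYP2C19, product: other, clint: 0.242}
in_vitro_reference:
  clint_rcyp3a4: 0.855            # uL/min/pmol, recombinant-enzyme assay
  clint_rcyp2c19: 0.614
  isef_cyp3a4: 0.21
  isef_cyp2c19: 0.25
dissolution:
  fasted: {t50_h: 0.942, shape: 0.990}
  fed:    {t50_h: 4.23,  shape: 0.502}
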