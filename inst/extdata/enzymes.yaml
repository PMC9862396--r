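# Enzyme expression defaults for the reference individual.
# reference_concentration is the hepatic (or mucosal) enzyme concentration
# in umol enzyme per L tissue.  The absolute abundances are not observable
# from plasma data alone; the bundled values were produced by
# calibrate_enzyme_abundance(), which pins them so that the simulated
# mass balance of a 50 mg oral dose apportions 71.6% of the dose to
# CYP3A4, 20.2% to CYP2C19 and the remainder to renal excretion.
# relative_expression ties the gut-mucosa CYP3A4 concentration to the
# hepatic one (gut = relative_expression x liver); it is preserved by
# calibration.
# kdeg: first-order enzyme degradation rate constants (1/h).  The model
# uses literature-typical turnover half-lives (CYP3A4 liver ~ 36 h, gut
# ~ 23 h, CYP2C19 ~ 26 h); these are configuration entries, and DDI
# magnitudes depend on them.
enzymes:
  - enzyme: CYP3A4
    organ: liver
    reference_concentration_umol_L: 4.5318
    relative_expression: 1.0
    kdeg_per_h: 0.019
  - enzyme: CYP3A4
    organ: gut
    reference_concentration_umol_L: 0.67978
    relative_expression: 0.15
    kdeg_per_h: 0.030
  - enzyme: CYP2C19
    organ: liver
    reference_concentration_umol_L: 1.06121
    relative_expression: 1.0
    kdeg_per_h: 0.0267
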