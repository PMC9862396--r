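# Simplified rifampicin perpetrator model: Emax induction of CYP3A4
# de-novo synthesis plus a one-compartment oral description of the
# perpetrator's own kinetics.
# Provenance of the interaction parameters (not printed in the tegoprazan
# study; taken from the induction literature):
#   Emax, EC50: in-vivo calibrated CYP3A4 induction by rifampicin,
#     Emax ~ 9, EC50 ~ 0.34 umol/L, as used in published PBPK DDI models
#     of rifampicin (Hanke et al., CPT:PSP 2018; Almond et al. 2016).
# Own kinetics: 600 mg oral rifampicin, CL/F ~ 7 L/h, V/F ~ 55 L,
# ka ~ 1.15 /h, fu ~ 0.17 (Acocella, Clin Pharmacokinet 1978).
# Autoinduction of rifampicin's own clearance is not modelled.
name: rifampicin
mechanism: induction
Emax: 9
EC50_umol_L: 0.34
own_kinetics:
  molecular_weight: 822.94  # g/mol
  ka_per_h: 1.15
  volume_L: 55
  clearance_L_per_h: 7
  fu_plasma: 0.17
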