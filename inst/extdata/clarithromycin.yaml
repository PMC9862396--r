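# Simplified clarithromycin perpetrator model: mechanism-based
# inactivation (MBI) of CYP3A4 plus a one-compartment oral description of
# the perpetrator's own kinetics.
# Provenance of the interaction parameters (not printed in the tegoprazan
# study; taken from the MBI literature):
#   KI, kinact: human liver microsome mechanism-based inactivation of
#     CYP3A4 by clarithromycin, KI ~ 5.49 umol/L, kinact ~ 0.042 /min,
#     as reported by Mayhew et al. (Drug Metab Dispos 2000) and adopted
#     in published DDI prediction work (Ito et al. 2003; Obach et al. 2007).
# Own kinetics: 500 mg oral clarithromycin, CL/F ~ 31 L/h, V/F ~ 191 L,
# ka ~ 0.6 /h, fu ~ 0.30 (Rodvold, Clin Pharmacokinet 1999).
name: clarithromycin
mechanism: mbi
KI_umol_L: 5.49
kinact_per_h: 2.52          # 0.042 /min
own_kinetics:
  molecular_weight: 747.95  # g/mol
  ka_per_h: 0.6
  volume_L: 191
  clearance_L_per_h: 31
  fu_plasma: 0.30
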