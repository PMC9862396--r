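# Reference adult male physiology (73.5 kg, ~30 y): organ volumes, blood
# flows and bulk composition fractions used by the whole-body model.
# Values are rounded ICRP-style reference-man quantities expressed on a
# plasma-flow-equivalent basis (blood:plasma partition assumed 1).
# Conventions:
#   - 'liver' flow is the hepatic arterial supply only; the portal inflow
#     is the sum of the 'gut' and 'spleen' flows and is routed through the
#     liver by the engine.
#   - 'lung' flow is total cardiac output; 'arterial'/'venous' are the
#     blood pools and carry no flow entry of their own.
#   - non-lung organ flows sum exactly to cardiac output (390 L/h).
organ	volume_L	flow_L_per_h	water_fraction	lipid_fraction	protein_fraction
adipose	14.0	19.5	0.18	0.792	0.05
bone	10.5	19.5	0.44	0.0751	0.20
brain	1.45	46.8	0.77	0.1075	0.08
heart	0.33	15.6	0.78	0.0251	0.15
kidney	0.31	74.1	0.78	0.0362	0.15
muscle	29.0	66.3	0.76	0.0172	0.17
skin	3.3	19.5	0.72	0.0644	0.25
rest	2.5	44.7	0.76	0.05	0.15
gut	1.2	46.8	0.76	0.0653	0.15
spleen	0.15	11.7	0.78	0.019	0.18
liver	1.8	25.5	0.74	0.038	0.18
lung	0.5	390	0.81	0.036	0.15
arterial	1.8	0	0.945	0.0036	0.08
venous	3.6	0	0.945	0.0036	0.08
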