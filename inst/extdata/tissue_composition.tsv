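# Tissue composition for partition-coefficient prediction: fractional
# volumes of water, neutral lipid and phospholipid per organ, plus plasma.
# Values follow the published tissue-composition tables commonly used with
# the Poulin-Theil family of Kp methods.
organ	f_water	f_neutral_lipid	f_phospholipid
adipose	0.18	0.79	0.002
bone	0.44	0.074	0.0011
brain	0.77	0.051	0.0565
gut	0.76	0.049	0.0163
heart	0.78	0.014	0.0111
kidney	0.78	0.012	0.0242
liver	0.74	0.014	0.024
lung	0.81	0.022	0.014
muscle	0.76	0.010	0.0072
skin	0.72	0.060	0.0044
spleen	0.78	0.0077	0.0113
rest	0.76	0.040	0.010
plasma	0.96	0.0023	0.0013
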