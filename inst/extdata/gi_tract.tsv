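# Gastrointestinal tract discretisation: stomach, four small-intestinal
# segments and a colon, with first-order transit.  Undissolved and
# dissolved material transit together and dissolution continues in every
# segment; absorption takes place from the dissolved pool of the
# intestinal segments (the stomach multiplier is zero; material leaving
# the colon is counted as unabsorbed).  surface_area_cm2 is the smooth
# cylindrical area; effective_area_multiplier folds in mucosal
# amplification (folds, villi).  transit_rate_per_h for the stomach is
# the fasted gastric emptying rate (t1/2 ~ 15 min); meals scale it
# transiently (see meal_event()).
segment	volume_L	pH	transit_rate_per_h	surface_area_cm2	effective_area_multiplier
stomach	0.25	1.5	2.8	500	0
duodenum	0.105	6.0	1.2	170	850
jejunum_upper	0.105	6.5	1.2	750	580
jejunum_lower	0.105	7.0	1.2	750	580
ileum	0.105	7.4	1.2	750	270
colon	0.4	6.5	0.042	5000	25
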