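key	value
maternal_autosomal_events	119
paternal_autosomal_events	186
autosomal_events	305
z_events	20
z_maternal_par_events	2
meioses_per_sex	5
female_rate_cM_per_Mb	2.28
male_rate_cM_per_Mb	3.56
par_length_Mb	0.6
nco_events	267
nco_ws_sites	229
nco_ws_fraction	0.59
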