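locality,sex,age_band,n,diet_ug_day
Bangkok,male,20-39,85,56
Bangkok,male,40-59,31,50
Bangkok,female,20-39,117,27
Bangkok,female,40-59,81,21
MaeSot,male,13-19,152,234
MaeSot,male,20-39,191,224
MaeSot,male,40-59,327,188
MaeSot,male,60+,151,167
MaeSot,female,13-19,221,132
MaeSot,female,20-39,903,113
MaeSot,female,40-59,1394,99
MaeSot,female,60+,358,118
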