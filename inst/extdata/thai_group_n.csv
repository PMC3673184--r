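locality,sex,age_band,smoking_category,n
Bangkok,male,20-39,never,85
Bangkok,male,40-59,never,31
Bangkok,female,20-39,never,117
Bangkok,female,40-59,never,81
MaeSot,male,13-19,never,152
MaeSot,male,20-39,never,191
MaeSot,male,40-59,never,327
MaeSot,male,60+,never,151
MaeSot,female,13-19,never,221
MaeSot,female,20-39,never,903
MaeSot,female,40-59,never,1394
MaeSot,female,60+,never,358
Bangkok,male,20-39,light_moderate,65
Bangkok,male,40-59,light_moderate,12
MaeSot,male,13-19,heavy,55
MaeSot,male,20-39,heavy,296
MaeSot,male,40-59,heavy,663
MaeSot,male,60+,heavy,277
MaeSot,female,20-39,heavy,38
MaeSot,female,40-59,heavy,207
MaeSot,female,60+,heavy,162
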