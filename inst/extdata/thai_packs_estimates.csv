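locality,sex,age_band,smoking_category,n,packs_per_day
Bangkok,male,20-39,light_moderate,65,1.0
Bangkok,male,40-59,light_moderate,12,3.7
MaeSot,male,13-19,heavy,55,1.5
MaeSot,male,20-39,heavy,296,1.5
MaeSot,male,40-59,heavy,663,3.0
MaeSot,male,60+,heavy,277,4.0
MaeSot,female,20-39,heavy,38,4.0
MaeSot,female,40-59,heavy,207,4.0
MaeSot,female,60+,heavy,162,4.0
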