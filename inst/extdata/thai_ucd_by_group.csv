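locality,sex,age_band,smoking_category,gm,sd
Bangkok,male,13-19,never,0.30,0.10
Bangkok,male,20-39,never,0.33,0.36
Bangkok,male,40-59,never,0.49,0.38
Bangkok,female,13-19,never,0.35,0.22
Bangkok,female,20-39,never,0.48,0.43
Bangkok,female,40-59,never,0.54,0.51
Bangkok,male,13-19,light_moderate,0.28,0.32
Bangkok,male,20-39,light_moderate,0.41,0.41
Bangkok,male,40-59,light_moderate,0.92,0.93
MaeSot,male,13-19,never,0.70,0.84
MaeSot,male,20-39,never,1.04,1.61
MaeSot,male,40-59,never,1.50,1.98
MaeSot,male,60+,never,1.85,2.47
MaeSot,female,13-19,never,0.95,1.36
MaeSot,female,20-39,never,1.49,2.26
MaeSot,female,40-59,never,2.08,2.82
MaeSot,female,60+,never,3.07,3.79
MaeSot,male,13-19,former,0.45,0.46
MaeSot,male,20-39,former,0.99,1.54
MaeSot,male,40-59,former,1.78,3.11
MaeSot,male,60+,former,2.45,3.04
MaeSot,female,13-19,former,1.93,0.36
MaeSot,female,20-39,former,1.74,1.24
MaeSot,female,40-59,former,2.89,2.78
MaeSot,female,60+,former,3.70,3.09
MaeSot,male,13-19,light_moderate,0.72,0.54
MaeSot,male,20-39,light_moderate,1.00,1.15
MaeSot,male,40-59,light_moderate,2.07,1.78
MaeSot,male,60+,light_moderate,2.55,2.53
MaeSot,female,20-39,light_moderate,2.10,1.48
MaeSot,female,40-59,light_moderate,2.75,2.26
MaeSot,female,60+,light_moderate,3.13,3.73
MaeSot,male,13-19,heavy,0.79,0.61
MaeSot,male,20-39,heavy,1.17,1.51
MaeSot,male,40-59,heavy,2.12,2.54
MaeSot,male,60+,heavy,2.84,4.46
MaeSot,female,13-19,heavy,0.73,0.08
MaeSot,female,20-39,heavy,1.91,1.59
MaeSot,female,40-59,heavy,3.41,2.66
MaeSot,female,60+,heavy,3.92,3.46
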