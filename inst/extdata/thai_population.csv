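locality,sex,n_total,age_mean,age_sd,pct_never,pct_former,pct_light_moderate,pct_heavy,gm,sd
Bangkok,male,199,32.9,8.8,59.3,0,40.7,0,0.40,0.46
Bangkok,female,200,36.9,10,100,0,0,0,0.50,0.46
MaeSot,male,3021,47.7,16.6,27.2,20.9,9.2,42.7,1.65,2.40
MaeSot,female,3726,46.4,15.2,77.2,7.4,4.4,11.0,2.10,2.91
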