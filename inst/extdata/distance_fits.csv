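treatment,n,family,shape,scale,ac,ac_ci_lower,ac_ci_upper
control,187,gompertz,0.0728,0.0094,0.92,0.87,0.95
WOC,78,gompertz,0.0589,0.0066,0.72,0.37,0.90
TIMR,31,gompertz,0.038,0.0001,NA,NA,NA
TIMR + WOC,109,gompertz,0.0441,0.0055,0.52,0.19,0.87
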