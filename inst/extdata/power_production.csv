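treatment,mean_wind_mps,energy_mwh_per_turbine,revenue_per_turbine
control,5.8,606.3,24253.80
WOC,5.7,574.1,22962.04
TIMR,5.6,516.5,20661.96
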