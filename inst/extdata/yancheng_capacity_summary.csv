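year,mean_ex,area_high_km2,area_low_km2
1980,0.85,39.67,17.54
2017,0.65,11.34,71.62
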