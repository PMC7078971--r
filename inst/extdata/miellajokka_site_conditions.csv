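site,elevation_m,catchment_km2,strahler_order,discharge_ls,discharge_q05,discharge_q95,temperature_c,temperature_q05,temperature_q95,pco2_ppm,pco2_q05,pco2_q95
M1,381,51.5,4,1513,643,3849,7.6,5.2,10,1130,910,1320
M6,747,1.8,2,101,47,247,6.1,3.8,8.4,840,610,1120
M9,800,10.9,2,654,316,1080,8.1,4.1,11.9,880,650,1100
M10,815,8.6,3,361,287,482,7.2,4.6,10.2,740,460,1080
M16,385,0.7,2,128,71,208,6.9,5.1,8.3,1990,1700,2230
M17,706,0.11,1,14,9,18,5.4,1.5,8.7,2460,1900,3100
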