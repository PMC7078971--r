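site,n_days,nep,nep_q05,nep_q95,gpp,gpp_q05,gpp_q95,er,er_q05,er_q95,evasion,evasion_q05,evasion_q95,evasion_noon,evasion_midnight
M1,39,-2.4,-1.8,-3.7,0.21,0.09,0.38,-2.63,-1.9,-3.9,1.3,1.0,1.9,1.02,1.51
M6,132,-1.9,-0.8,-3.6,0.15,0.04,0.33,-2.08,-0.9,-3.9,1.5,0.8,2.2,1.53,1.55
M9,135,-1.4,-0.5,-3.5,0.24,0.07,0.69,-1.29,-0.5,-2.6,1.3,0.4,3.2,1.21,1.52
M10,88,-1.3,-0.4,-2.7,0.28,0.05,0.62,-1.61,-0.6,-3.2,0.8,0.3,1.4,0.75,0.93
M16,46,-2.1,-1.3,-3.7,0.24,0.11,0.43,-2.37,-1.5,-3.9,2.7,1.5,4.9,2.19,3.01
M17,53,-1.2,-0.5,-1.9,0.19,0.06,0.36,-1.35,-0.6,-2.2,1.4,0.6,2.2,1.26,1.67
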