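species,activity,unit
HCO3-,2.020e-2,M
CH4,3.000e-5,M
SO4-2,5.200e-3,M
H2S,8.000e-4,M
Fe+2,3.000e-5,M
NO3-,1.850e-4,M
NO2-,1.160e-5,M
PCE,3.190e-7,M
TCE,7.290e-7,M
Cl-,1.690e-2,M
acetate-,1.000e-4,M
cDCE,4.570e-7,M
pH,7,unitless
temperature,298.15,K
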