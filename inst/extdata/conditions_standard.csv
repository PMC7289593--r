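species,activity,unit
H2,1,atm
CH4,1,atm
HCO3-,1,M
acetate-,1,M
SO4-2,1,M
H2S,1,M
Fe+2,1,M
NO3-,1,M
NO2-,1,M
Cl-,1,M
PCE,1,M
TCE,1,M
cDCE,1,M
DCA,1,M
ethene,1,M
MCB,1,M
benzene,1,M
2-CP,1,M
phenol,1,M
pH,7,unitless
temperature,298.15,K
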