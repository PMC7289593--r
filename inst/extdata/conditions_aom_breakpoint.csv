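species,activity,unit
CH4,2.14,atm
HCO3-,2.020e-2,M
pH,7,unitless
temperature,298.15,K
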