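name,phase,charge,henry_mol_m3_Pa
H2,gas,0,7.8e-06
CH4,gas,0,1.4e-05
H2O,water,0,
H+,aqueous,1,
HCO3-,aqueous,-1,
acetate-,aqueous,-1,
SO4-2,aqueous,-2,
H2S,aqueous,0,
Fe(OH)3,solid,0,
Fe+2,aqueous,2,
NO3-,aqueous,-1,
NO2-,aqueous,-1,
Cl-,aqueous,-1,
PCE,aqueous,0,
TCE,aqueous,0,
cDCE,aqueous,0,
DCA,aqueous,0,
ethene,aqueous,0,
MCB,aqueous,0,
benzene,aqueous,0,
2-CP,aqueous,0,
phenol,aqueous,0,
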