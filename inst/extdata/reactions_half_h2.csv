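id,equation,dg0_prime_kj,ref_species,donor,acceptor,n_electrons
pce_to_tce,PCE(aq) + H2(g) -> TCE(aq) + H+(aq) + Cl-(aq),-173.3,PCE,H2,PCE,2
tce_to_cdce,TCE(aq) + H2(g) -> cDCE(aq) + H+(aq) + Cl-(aq),-168.8,TCE,H2,TCE,2
cp_to_phenol,2-CP(aq) + H2(g) -> phenol(aq) + H+(aq) + Cl-(aq),-152.9,2-CP,H2,2-CP,2
mcb_to_benzene,MCB(aq) + H2(g) -> benzene(aq) + H+(aq) + Cl-(aq),-153.3,MCB,H2,MCB,2
dca_to_ethene,DCA(aq) + H2(g) -> ethene(aq) + 2 H+(aq) + 2 Cl-(aq),-247.2,DCA,H2,DCA,2
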