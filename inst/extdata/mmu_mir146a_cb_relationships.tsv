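gene_a	regulator	gene_b	secondary	log2fc	pvalue	prevalence
bach2	mmu-miR-146a-5p	mcm5	mmu-miR-16-5p	0.611762	0.000437	39
mmd	mmu-miR-146a-5p	mcm5	mmu-miR-16-5p	0.611762	0.000437	39
rbl1	mmu-miR-146a-5p	mcm5	mmu-miR-16-5p	0.611762	0.000437	39
irf4	mmu-miR-146a-5p	mcm5	mmu-miR-16-5p	0.611762	0.000437	39
bach2	mmu-miR-146a-5p	ncapg2	mmu-miR-16-5p	0.611762	0.000437	39
mmd	mmu-miR-146a-5p	ncapg2	mmu-miR-16-5p	0.611762	0.000437	39
rbl1	mmu-miR-146a-5p	ncapg2	mmu-miR-16-5p	0.611762	0.000437	39
irf4	mmu-miR-146a-5p	ncapg2	mmu-miR-16-5p	0.611762	0.000437	39
irf4	mmu-miR-146a-5p	mcm4	mmu-miR-23b-3p	0.295528	0.02836	21
bach2	mmu-miR-146a-5p	mcm4	mmu-miR-23b-3p	0.295528	0.02836	21
rbl1	mmu-miR-146a-5p	mcm4	mmu-miR-23b-3p	0.295528	0.02836	21
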