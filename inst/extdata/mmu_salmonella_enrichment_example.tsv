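set_id	description	k	n	K	N	printed_pvalue
mmu05132	Salmonella infection	15	170	253	8900	9.57e-05
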