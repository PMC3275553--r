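chrom	length	n_protein_coding_genes	n_alleles	n_genes_within
I	15072	2906	2662	1220
II	15279	3540	2201	1538
III	13784	2685	1589	1007
IV	17494	3321	2445	1302
V	20920	5134	2851	2141
X	17719	2828	2552	1276
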