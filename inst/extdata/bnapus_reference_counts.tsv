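quantity	count
genes_total	94013
genes_core	58532
genes_variable	35481
clusters_total	43327
clusters_core	28239
clusters_variable	15088
rgenes_total	307
rgenes_core	94
rgenes_variable	213
rgenes_new_contig	146
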