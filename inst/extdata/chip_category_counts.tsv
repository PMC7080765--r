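category	n_genes	total_length_bp	n_snps	n_genes_chip	n_snps_chip
SCP	10064	12218733	430380	4314	24537
CSCSP	5899	18726973	130439	4328	27291
AGCP	192	617039	13979	156	1536
DRDRP	874	2907123	48387	746	8090
MCP	96	201088	22477	85	599
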