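name	adapter_tail	gene_specific
etr-1PCR1F	CGACAGGTTCAGAGTTCTACAGTCCGACGATC	cccacggtcgcaatatccgattc
etr-1PCR1R	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	tgatgatgtgaagccgacgatg
mab-5PCR1F	CGACAGGTTCAGAGTTCTACAGTCCGACGATC	catcccctcaactcaatccgtcg
mab-5PCR1R	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	agcagcggcagcactagacgatg
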