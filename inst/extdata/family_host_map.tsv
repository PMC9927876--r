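family	host_kingdom
Narnaviridae	Eukaryota
Mitoviridae	Eukaryota
Leviviridae	Bacteria
Totiviridae	Eukaryota
Partitiviridae	Eukaryota
Marnaviridae	Eukaryota
Qinviridae	Eukaryota
Amalgaviridae	Eukaryota
Botourmiaviridae	Eukaryota
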