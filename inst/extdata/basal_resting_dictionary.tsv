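cell_cluster	marker_gene	n_votes	votes_total	percent
Basal resting	TP63	4	21	4/21
Basal resting	KRT5	4	21	4/21
Basal resting	KRT15	3	21	1/7
Basal resting	FXYD3	2	21	2/21
Basal resting	KRT14	2	21	2/21
Basal resting	KRT17	2	21	2/21
Basal resting	EPCAM	1	21	1/21
Basal resting	ELF3	1	21	1/21
Basal resting	IGFBP2	1	21	1/21
Basal resting	SERPINF1	1	21	1/21
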