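gene	match_mode	targets	drug	direction	level	note
KRAS	codon_set	G12,G13,A59,Q61,K117,A146	Cetuximab	resistance	R1	anti-EGFR primary resistance
NRAS	codon_set	G12,G13,Q61	Panitumumab	resistance	R1	anti-EGFR primary resistance
BRAF	exact_protein_change	V600E	Encorafenib	sensitivity	L1	approved combination biomarker
KRAS	exact_protein_change	G12C	Adagrasib	sensitivity	L3	clinical-study evidence
KRAS	exact_protein_change	G12D	MRTX1133	sensitivity	L4	placeholder: laboratory evidence
PIK3CA	codon_set	E542,E545,H1047	Alpelisib	sensitivity	L4	placeholder: laboratory evidence
ATR	any_nonsynonymous		Berzosertib	sensitivity	L4	placeholder: laboratory evidence
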