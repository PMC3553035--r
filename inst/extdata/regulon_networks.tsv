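perturbation	direction	locus_tag	tf	size	fdr_q
genome_reduction	increased	b1951	rcsA	26	0.0000
genome_reduction	increased	b2217	rcsB	29	0.0000
genome_reduction	increased	b3938	metJ	15	0.0000
genome_reduction	increased	b3516	gadX	25	0.0000
genome_reduction	increased	b3512	gadE	49	0.0000
genome_reduction	increased	b0889	lrp	83	0.0038
genome_reduction	increased	b3461	rpoH	150	0.0065
genome_reduction	increased	b0761	modE	45	0.0061
genome_reduction	increased	b1237	hns	136	0.0145
genome_reduction	increased	b3261	fis	216	0.0513
genome_reduction	increased	b2193	narP	49	0.0870
genome_reduction	increased	b1221	narL	113	0.1043
genome_reduction	increased	b3912	cpxR	51	0.0972
genome_reduction	increased	b2531	iscR	26	0.1580
genome_reduction	increased	b0399	phoB	36	0.1572
genome_reduction	increased	b1712	ihfA	191	0.1477
genome_reduction	increased	b2741	rpoS	215	0.1448
genome_reduction	increased	b0912	ihfB	191	0.1398
genome_reduction	increased	b0076	leuO	20	0.1703
genome_reduction	increased	b1130	phoP	48	0.1627
genome_reduction	increased	b1334	fnr	272	0.1687
genome_reduction	increased	b1531	marA	36	0.2127
genome_reduction	decreased	b1658	purR	31	0.0071
genome_reduction	decreased	b0683	fur	81	0.0201
heat_shock	increased	b3461	rpoH	150	0.0000
heat_shock	increased	b3912	cpxR	51	0.0004
heat_shock	increased	b3938	metJ	15	0.0026
heat_shock	increased	b2193	narP	49	0.0837
heat_shock	increased	b0399	phoB	36	0.1384
heat_shock	increased	b0761	modE	45	0.2134
heat_shock	increased	b0076	leuO	20	0.2345
heat_shock	decreased	b1658	purR	31	0.0000
heat_shock	decreased	b1275	cysB	19	0.0000
heat_shock	decreased	b0683	fur	81	0.0000
heat_shock	decreased	b3516	gadX	25	0.0123
heat_shock	decreased	b3868	glnG	44	0.0118
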