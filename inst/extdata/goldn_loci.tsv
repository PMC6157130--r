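rsid	chrom	pos	gene	effect_allele	other_allele	eaf	n_cpgs_10kb	cpgs_included	expected_tg_direction	direction_source
rs1748195	1	63049593	DOCK7	G	C	0.636	1	cg00161770	1	convention
rs645040	3	135926622	RPL31P23/PCCB	A	C	0.807	2	cg15219878	1	reported
rs998584	6	43757896	VEGFA	C	A	0.543	6	cg03143046,cg01353538,cg20940044,cg25373579,cg23879496,cg12682870	1	convention
rs10503669	8	19847690	LPL	G	T	0.909	0	cg18449136	1	convention
rs964184	11	116154127	ZPR1/ZNF259	G	C	0.874	24	cg06595719,cg14815609,cg05862431,cg11835342,cg14371153,cg17490921	-1	reported
rs4765127	12	123026120	ZNF664	G	T	0.672	13	cg19078769,cg00201185,cg10922530,cg02647265	1	reported
rs4775041	15	58674695	Intergenic	G	C	0.720	1	cg25188724	1	convention
rs3198697	16	15129940	PDXDC1	C	T	0.569	5	cg16724811,cg06978461,cg03245889,cg03928410,cg26985681	1	convention
rs1121980	16	53809247	FTO	C	T	0.529	2	cg02252501,cg03312170	-1	reported
rs8077889	17	41878166	C17orf105/MPP3	T	G	0.798	2	cg13317831,cg01571583	1	convention
rs7248104	19	7224431	INSR	G	A	0.575	2	cg09779027,cg00428638	1	convention
rs10401969	19	19407718	SUGP1	A	G	0.929	5	cg00477287,cg01313994,cg01559787,cg08112740,cg19643441	1	reported
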