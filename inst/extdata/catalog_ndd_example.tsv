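kind	name	chrom	start	end	symbol	required_type	min_reciprocal_overlap
recurrent_locus	22q11.2	chr22	18880000	21460000		any	0.5
recurrent_locus	16p11.2_proximal	chr16	29560000	30110000		any	0.5
recurrent_locus	16p12.1_distal	chr16	21950000	22430000		DUP	0.5
recurrent_locus	15q11-q13	chr15	23680000	28390000		DUP	0.5
recurrent_locus	1q21.1_distal	chr1	146570000	147390000		any	0.5
recurrent_locus	15q11.2_BP1-BP2	chr15	22800000	23090000		any	0.5
significant_gene	NRXN1	chr2	50145000	51260000	NRXN1	any
significant_gene	ASTN2	chr9	119190000	120180000	ASTN2	any
significant_gene	CHD2	chr15	93430000	93570000	CHD2	DEL
susceptibility_gene	MACROD2	chr20	13970000	16030000	MACROD2	any
susceptibility_gene	DLGAP2	chr8	1440000	1660000	DLGAP2	any
susceptibility_gene	DLG2	chr11	83170000	85340000	DLG2	any
susceptibility_gene	DPP6	chr7	153580000	154690000	DPP6	any
susceptibility_gene	GRIK2	chr6	101840000	102520000	GRIK2	any
susceptibility_gene	CHAMP1	chr13	115000000	115110000	CHAMP1	any
susceptibility_gene	CNTN4	chr3	2140000	3100000	CNTN4	DUP
susceptibility_gene	CNTN6	chr3	1134000	1445000	CNTN6	DUP
susceptibility_gene	CYFIP1	chr15	22890000	23000000	CYFIP1	DUP
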