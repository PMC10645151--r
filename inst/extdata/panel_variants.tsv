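# Clinically actionable pharmacogene variant panel (GRCh37 coordinates).
# Columns mirror the source genotyping summary; Homozygotes/Heterozygotes are
# observed genotype counts in the 300-patient reference cohort and seed the
# default synthetic-cohort genotype frequencies. ZygosityRisk encodes the
# zygosity-dependent adverse-event risk rule where one is defined.
Gene	Chr	Position	Nucleotide	VariantID	Allele	Homozygotes	Heterozygotes	ZygosityRisk
CFTR	7	117227860	G > A	rs75527207	Gly551Asp	0	1
CYP2C19	10	96534922	G > C	rs17878459	*2B	0	9
CYP2C19	10	96541616	G > A	rs4244285	*2	10	75
CYP2C9	10	96702047	C > T	rs1799853	*2, *24, *35	5	56
CYP2C9	10	96741053	A > C	rs1057910	*3 and *18	3	46
CYP2D6	22	42524947	C > T	rs3892097	*4	9	45
CYP2D6	22	42525086	A > -	rs5030655	*6	0	4
CYP2D6	22	42526694	G > A	rs1065852	*10	12	73
DPYD	1	97547947	T > A	rs67376798	Asp949Val	0	5
DPYD	1	97915614	C > T	rs3918290	Splice donor	0	5
F5	1	169519049	C > T	rs6025	Arg534Gln	0	14
SLCO1B1	12	21331549	T > C	rs4149056	*5	7	82	het:moderate,hom:high
TPMT	6	18130918	T > C	rs1142345	*3A	2	27
TPMT	6	18139228	C > T	rs1800460	*3A	2	26
TPMT	6	18143955	C > G	rs1800462	*2	0	2
VKORC1	16	31104878	G > A	rs9934438	*2	40	136
VKORC1	16	31107689	C > T	rs9923231	*2	40	138
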