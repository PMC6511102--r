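# Newly identified STX1B variants (families F7-F23) with phenotype group
# (GEFS+: genetic epilepsy with febrile seizures plus; GGE: genetic
# generalized epilepsy; DEE: developmental and epileptic encephalopathy;
# FE: focal epilepsy) and inheritance.
# The F8, F17 and F18 variant pairings are inferred from group constraints
# (GEFS+ variants are all truncating; F17/F18 are de novo DEE), not stated
# explicitly in the source cohort description.
gene	hgvs_p	family_id	phenotype_group	inheritance
STX1B	p.Ser10Alafs*7	F7	GEFS+	de_novo
STX1B	p.Gln52Argfs*2	F8	GEFS+	inherited
STX1B	p.Arg245*	F9	GEFS+	unknown
STX1B	p.Tyr140*	F10	GEFS+	unknown
STX1B	p.Glu210Lys	F11	GGE	unknown
STX1B	p.Lys93*	F12	GGE	unknown
STX1B	p.Asn189Alafs*5	F13	DEE	unknown
STX1B	p.Ile282Thr	F14	DEE	de_novo
STX1B	p.Ser258Gln	F15	DEE	unknown
STX1B	p.Leu221Pro	F16	DEE	inherited
STX1B	p.Cys144Phe	F17	DEE	de_novo
STX1B	p.Thr285Aspfs*75	F18	DEE	de_novo
STX1B	p.Ala246Pro	F19	DEE	de_novo
STX1B	whole_gene_deletion	F20	DEE	inherited
STX1B	p.Glu128Glyfs*2	F21	DEE	unknown
STX1B	p.Arg261Gln	F22	FE	unknown
STX1B	p.Val88Phe	F23	FE	unknown
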