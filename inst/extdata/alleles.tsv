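allele_id	gene	label	species	hgvs_g	hgvs_c	hgvs_p	printed_codon	kind	classification	zygosity	case_ids	codon_consistent
COL2A1_bt_del	COL2A1	COL2A1 bovine 12bp deletion	Bos taurus	Chr5:g.32312706_32312718del	c.4432_4443del	p.(Gly1478_Ile1481del)		inframe_deletion	pathogenic	heterozygous	1	NA
COL2A1_oa_mis	COL2A1	COL2A1 ovine missense	Ovis aries	Chr3:g.138610131G>A	c.2908G>A	p.Gly970Ser	970	missense	pathogenic	heterozygous	2,3,4,5,6,7	TRUE
PPIB_bt_int	PPIB	PPIB intronic	Bos taurus	Chr10:g.45822912G>C	c.320-443G>C			intronic	uncertain	homozygous	8	NA
COL1A2_bt_mis	COL1A2	COL1A2 missense	Bos taurus	Chr4:g.11792118G>A	c.1156G>A	p.Gly386Arg	386	missense	pathogenic	heterozygous	9,10	TRUE
COL1A1_oa_mis	COL1A1	COL1A1 ovine missense	Ovis aries	Chr11:g.36197409G>A	c.1189G>A	p.Gly397Ser	397	missense	pathogenic	heterozygous	11,12,13	TRUE
LOC112445140_bt_stop	LOC112445140	DCAF12-like stop gained	Bos taurus	ChrX:g.10872688G>T	c.332C>A	p.Ser111*	111	stop_gained	pathogenic	heterozygous	14	TRUE
SLC40A1_bt_mis	SLC40A1	SLC40A1 missense	Bos taurus	Chr2:g.6785954T>A	c.323T>A	p.Ile108Asn	108	missense	pathogenic	heterozygous	15	TRUE
PTPN9_bt_mis	PTPN9	PTPN9 missense	Bos taurus	Chr21:g.33356490G>A	c.826G>A	p.Ala276Thr	276	missense	uncertain	heterozygous	17	TRUE
PRDM10_bt_mis	PRDM10	PRDM10 missense	Bos taurus	Chr29:g.36138136G>A	c.866C>T	p.Pro289Leu	289	missense	pathogenic	heterozygous	18,19	TRUE
PDGFRA_bt_mis	PDGFRA	PDGFRA missense	Bos taurus	Chr6:g.69749162T>C	c.1685T>C	p.Ile562Thr	562	missense	pathogenic	heterozygous	21	TRUE
ABCC8_bt_mis	ABCC8	ABCC8 missense	Bos taurus	Chr15:g.35095352A>G	c.2875A>G	p.Met959Val	959	missense	likely_pathogenic	heterozygous	22	TRUE
LRP4_holstein_1	LRP4	LRP4 Holstein allele 1	Bos taurus	Chr15:g.76800972CdelinsAT	c.4863_4864delinsAT	p.Asn1621_Gly1622delinsLysCys		delins	pathogenic	compound-partner	26,27	NA
LRP4_holstein_2	LRP4	LRP4 Holstein allele 2	Bos taurus	Chr15:g.76800896G>A	c.4940C>T	p.Pro1647Leu	1647	missense	pathogenic	compound-partner	26	TRUE
LRP4_holstein_3	LRP4	LRP4 Holstein allele 3	Bos taurus	Chr15:g.76819481G>A	c.1480C>T	p.Arg494Cys	494	missense	pathogenic	compound-partner	27	TRUE
KMT2C_bt_mis	KMT2C	KMT2C missense	Bos taurus	Chr4:g.114640130G>T	c.6031C>A	p.Pro2011Thr	2011	missense	uncertain	homozygous	28	TRUE
CD4_bt_mis	CD4	CD4 missense	Bos taurus	Chr5:g.103647362G>A	c.59C>T	p.Pro20Leu	20	missense	uncertain	homozygous	29	TRUE
CCT3_bt_mis	CCT3	CCT3 missense	Bos taurus	Chr3:g.14497551T>C	c.907T>C	p.Tyr303His	303	missense	likely_pathogenic	heterozygous	32	TRUE
ITGAE_bt_mis	ITGAE	ITGAE missense	Bos taurus	Chr19:g.24423519A>G	c.986T>C	p.Ile329Thr	329	missense	likely_pathogenic	homozygous	33	TRUE
CNTNAP1_bt_mis	CNTNAP1	CNTNAP1 allele 1	Bos taurus	Chr19:g.42747176G>A	c.1495G>A	p.Ala734Thr	734	missense	likely_pathogenic	compound-partner	34	FALSE
CNTNAP1_bt_int	CNTNAP1	CNTNAP1 allele 2	Bos taurus	Chr19:g.42748559G>A	c.2531-52G>A			intronic	likely_pathogenic	compound-partner	34	NA
NFE2L1_bt_del	NFE2L1	NFE2L1 in-frame deletion	Bos taurus	Chr19:g.38426902AAGG>A	c.531_533delCCT	p.Leu178del		inframe_deletion	likely_pathogenic	heterozygous	35	NA
IL16_bt_mis	IL16	IL16 missense	Bos taurus	Chr21:g.27078178A>G	c.1624A>G	p.Asn542Asp	542	missense	likely_pathogenic	heterozygous	36	TRUE
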