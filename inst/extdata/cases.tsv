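category	disorder	species	breed	gene	moi	variant_type	classification	case_ids	design	notes
Type 2 collagen disorders	Achondrogenesis, type II	Bos taurus	Holstein	COL2A1	AD	heterozygous, small frameshift deletion	pathogenic	1	trio	in-frame 12 bp deletion (4 residues) despite the frameshift label
Type 2 collagen disorders	Achondrogenesis, type II	Ovis aries	Crossbred	COL2A1	AD	heterozygous, missense	pathogenic	2,3,4,5,6,7	single_parent	paternal half-sibs; inherited from germline-mosaic sire
Osteogenesis imperfecta and bone fragility group	Osteogenesis imperfecta	Bos taurus	Holstein	PPIB	AR	homozygous, intronic	uncertain	8	trio
Osteogenesis imperfecta and bone fragility group	Osteogenesis imperfecta	Bos taurus	Stabiliser	COL1A2	AD	heterozygous, missense	pathogenic	9,10	trio
Osteogenesis imperfecta and bone fragility group	Osteogenesis imperfecta	Ovis aries	Crossbred	COL1A1	AD	heterozygous, missense	pathogenic	11,12,13	single_parent	inherited from germline-mosaic sire
Osteopetrosis and related osteoclast disorders	Osteopetrosis and brachignatia inferior	Bos taurus	Crossbred	LOC112445140	XLD	heterozygous, stop gained	pathogenic	14	trio
Sulfation disorders	Caudal and thoracic vertebral and viscerocranial malformations	Bos taurus	Holstein	SLC40A1	AD	heterozygous, missense	pathogenic	15	trio
Primordial dwarfism and slender bones group	Primordial proportionate dwarfism	Bos taurus	Simmental				none	16	trio
Primordial dwarfism and slender bones group	Primordial proportionate dwarfism	Bos taurus	Simmental	PTPN9	AD	heterozygous, missense	uncertain	17	single_case
Primordial dwarfism and slender bones group	Primordial disproportionate dwarfism	Bos taurus	Angus	PRDM10	AD	heterozygous, missense	pathogenic	18,19	multiple_cases
Primordial dwarfism and slender bones group	Primordial disproportionate dwarfism	Bos taurus	Holstein				none	20	single_case
Primordial dwarfism and slender bones group	Primordial disproportionate dwarfism with craniofacial dysmorphism	Bos taurus	Holstein	PDGFRA	AD	heterozygous, missense	pathogenic	21	single_case
Primordial dwarfism and slender bones group	Primordial disproportionate dwarfism	Bos taurus	Crossbred	ABCC8	AD	heterozygous, missense	likely_pathogenic	22	single_case	table says disproportionate; the case text says proportionate dwarfism
Primordial dwarfism and slender bones group	Arachnomelia	Bos taurus	Holstein				none	23	trio
Primordial dwarfism and slender bones group	Craniofacial dysmorphism-hydrocephalus-dwarfism syndrome	Bos taurus	Angus	Trisomy 23	AD	aneuploidy	pathogenic	24	trio	paternal non-disjunction
Polydactyly-Syndactyly-Triphalangism	Polydactyly	Bos taurus	Crossbred	Partial monosomy chr28	AD	aneuploidy	pathogenic	25	trio	terminal ~2.7 Mb loss, paternal
Polydactyly-Syndactyly-Triphalangism	Syndactyly	Bos taurus	Holstein	LRP4	AR	compound heterozygous, small frameshift insertion, missense	pathogenic	26	trio
Polydactyly-Syndactyly-Triphalangism	Syndactyly	Bos taurus	Holstein	LRP4	AR	compound heterozygous, small frameshift insertion, missense	pathogenic	27	single_parent
Polydactyly-Syndactyly-Triphalangism	Syndactyly	Bos taurus	Holstein	KMT2C	AR	homozygous, missense	uncertain	28	single_case
Polydactyly-Syndactyly-Triphalangism	Syndactyly	Bos taurus	Droughtmaster	CD4	AR	homozygous, missense	uncertain	29	single_case	sire homozygous wildtype; parentage unverified
Disorders of bone mineralisation	Congenital rickets	Bos taurus	Angus				none	30,31	multiple_cases
Dysplasias with multiple joint dislocations	Craniofacial dysmorphisms, and forelimbs skeletal dysplasia	Bos taurus	Holstein	CCT3	AD	heterozygous, missense	likely_pathogenic	32	single_case
Dysplasias with multiple joint dislocations	Craniofacial dysmorphisms, forelimbs dislocations and skeletal dysplasia	Bos taurus	Holstein	ITGAE	AR	homozygous, missense	likely_pathogenic	33	single_case
Dysplasias with multiple joint dislocations	Craniofacial dysmorphism, forelimbs dysplasia with joint contracture	Bos taurus	Chianina	CNTNAP1	AR	compound heterozygous, missense, intronic	likely_pathogenic	34	single_case
Dysplasias with multiple joint dislocations	Forelimbs dysplasia with joint contracture	Bos taurus	Holstein	NFE2L1	AD	heterozygous, small disruptive inframe deletion	likely_pathogenic	35	single_case
Dysplasias with multiple joint dislocations	Forelimbs dysplasia with joint contracture	Bos taurus	Chianina	IL16	AD	heterozygous, missense	likely_pathogenic	36	single_parent
Dysplasias with multiple joint dislocations	Forelimbs dysplasia with joint contracture	Bos taurus	Limousin				none	37,38	trio
Vertebral and costal dysostoses	Hemifacial microsomia with hemivertebrae	Bos taurus	Rendena				none	39	single_case
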