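# chipdyn default CHIP panel, representative GRCh38-style intervals (0-based half-open)
chr1	1787300	1788400	GNB1
chr1	43348900	43350800	MPL
chr1	114716000	114716600	NRAS
chr2	25234300	25235300	DNMT3A
chr2	25240200	25241100	DNMT3A
chr2	25247000	25248000	DNMT3A
chr2	25733500	25735600	ASXL2
chr2	25740000	25742100	ASXL2
chr2	197400200	197402200	SF3B1
chr2	197405000	197406900	SF3B1
chr2	208248000	208248700	IDH1
chr4	54727200	54728600	KIT
chr4	54733100	54734600	KIT
chr4	105145800	105149000	TET2
chr4	105190500	105193400	TET2
chr9	5073600	5075100	JAK2
chr11	119206200	119207600	CBL
chr11	119227800	119229200	CBL
chr12	22655500	22656900	ETNK1
chr12	25245000	25245600	KRAS
chr15	90088100	90089000	IDH2
chr17	7673500	7674800	TP53
chr17	60656600	60658400	PPM1D
chr17	76736600	76737300	SRSF2
chr18	44680000	44684600	SETBP1
chr20	32433200	32434500	ASXL1
chr20	32435500	32436800	ASXL1
chr20	58903500	58905700	GNAS
chr21	43092500	43093300	U2AF1
chrX	155071500	155072500	BRCC3
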