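name	recognition	top_cut_offset	bottom_cut_offset	cut_inside
BsaI	GGTCTC	1	5	0
HindIII	AAGCTT	1	5	1
XbaI	TCTAGA	1	5	1
EcoRI	GAATTC	1	5	1
SacI	GAGCTC	5	1	1
SacII	CCGCGG	4	2	1
PstI	CTGCAG	5	1	1
BamHI	GGATCC	1	5	1
XhoI	CTCGAG	1	5	1
SalI	GTCGAC	1	5	1
PmeI	GTTTAAAC	4	4	1
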