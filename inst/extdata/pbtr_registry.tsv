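name	set	category	plant_marker	fwd_adapter	rev_adapter	ovh_upstream	ovh_downstream
pH35BTR1	BTR1	overexpression_35S	HygR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pK35BTR1	BTR1	overexpression_35S	KanR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pR35BTR1	BTR1	overexpression_35S	DsRed	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pH35BTR2	BTR2	overexpression_35S	HygR	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
pK35BTR2	BTR2	overexpression_35S	KanR	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
pR35BTR2	BTR2	overexpression_35S	DsRed	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
pBUbiBTR1	BTR1	overexpression_Ubi	BarR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pHUbiBTR1	BTR1	overexpression_Ubi	HygR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pKUbiBTR1	BTR1	overexpression_Ubi	KanR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pBUbiBTR2	BTR2	overexpression_Ubi	BarR	NNNNGGTCTCNCAGA	NNNNGGTCTCNGCTC	TCTG	GAGC
pHUbiBTR2	BTR2	overexpression_Ubi	HygR	NNNNGGTCTCNCAGA	NNNNGGTCTCNGCTC	TCTG	GAGC
pKUbiBTR2	BTR2	overexpression_Ubi	KanR	NNNNGGTCTCNCAGA	NNNNGGTCTCNGCTC	TCTG	GAGC
pHNatBTR1	BTR1	native_promoter	HygR	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCC	AAGC	GGAT
pKNatBTR1	BTR1	native_promoter	KanR	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCC	AAGC	GGAT
pRNatBTR1	BTR1	native_promoter	DsRed	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCC	AAGC	GGAT
pHNatBTR2	BTR2	native_promoter	HygR	NNNNGGTCTCNCTTT	NNNNGGTCTCNTCCT	AAAG	AGGA
pKNatBTR2	BTR2	native_promoter	KanR	NNNNGGTCTCNCTTT	NNNNGGTCTCNTCCT	AAAG	AGGA
pRNatBTR2	BTR2	native_promoter	DsRed	NNNNGGTCTCNCTTT	NNNNGGTCTCNTCCT	AAAG	AGGA
pHBTR1PGUS	BTR1	promoter_GUS	HygR	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCT	AAGC	AGAT
pKBTR1PGUS	BTR1	promoter_GUS	KanR	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCT	AAGC	AGAT
pRBTR1PGUS	BTR1	promoter_GUS	DsRed	NNNNGGTCTCNGCTT	NNNNGGTCTCNATCT	AAGC	AGAT
pHBTR2PGUS	BTR2	promoter_GUS	HygR	NNNNGGTCTCNCTTT	NNNNGGTCTCNAGAA	AAAG	TTCT
pKBTR2PGUS	BTR2	promoter_GUS	KanR	NNNNGGTCTCNCTTT	NNNNGGTCTCNAGAA	AAAG	TTCT
pRBTR2PGUS	BTR2	promoter_GUS	DsRed	NNNNGGTCTCNCTTT	NNNNGGTCTCNAGAA	AAAG	TTCT
pK35BTR1GFP	BTR1	subcellular_GFP	KanR	NNNNGGTCTCNGATG	NNNNGGTCTCNCTCC	CATC	GGAG
pK35BTR2GFP	BTR2	subcellular_GFP	KanR	NNNNGGTCTCNTAGA	NNNNGGTCTCNCACC	TCTA	GGTG
pSKBTR1	BTR1	empty_SBTR	KanR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pSHBTR1	BTR1	empty_SBTR	HygR	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pSRBTR1	BTR1	empty_SBTR	DsRed	NNNNGGTCTCNGATG	NNNNGGTCTCNATCC	CATC	GGAT
pSKBTR2	BTR2	empty_SBTR	KanR	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
pSHBTR2	BTR2	empty_SBTR	HygR	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
pSRBTR2	BTR2	empty_SBTR	DsRed	NNNNGGTCTCNTAGA	NNNNGGTCTCNGCTC	TCTA	GAGC
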