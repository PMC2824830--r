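mode	space_group	sequence	cation	angle_deg	entry_id
Major-groove/backbone	R 3	AC[C]GG[C]GCCACA	Mg2+	79	BD0022
Major-groove/backbone	R 3	[C][C]GC[C]GGCGG	Mg2+	78	BD0015
Major-groove/backbone	C 1 2 1	[C]TCTCGAGAG	Ca2+	42	BDJ060
Major-groove/backbone	C 1 2 1	C(C)GCTAGCGG		50	BD0028
Major-groove/backbone	C 1 2 1	C(C)TCTAGAGG		46	BD0076
Major-groove/backbone	P 31 2 1	GCAAA[C]GTTTGC		61	BD0047
Minor-groove/backbone	C 1 2 1	CGCAATTGCG		38	BDJ069
Major <> Major	C 1 2 1	CTCTCGAGAG		-42	BDJ060
Major <> Major	C 1 2 1	CCGCTAGCGG		-50	BD0028
Major <> Major	C 1 2 1	CCTCTAGAGG		-46	BD0076
Minor <> Minor	P 31	CCGAGCTCGG		-60	BD0084
Major <> Minor	R 3	CCGCCGGCGG		-78	BD0015
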