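# glycomine-kb v1 curated training pairs (20-molecule benchmark reconstruction)
pair_id	molecule	monomer_ids	present_classes
tp01	avilamycin	s17,s17,s18,s18,s20,p01,p02	gc01,gc02,gc31,gc34,gc37,gc45
tp02	deoxystreptamine	s04	gc14,gc15,gc16,gc39
tp03	acarbose	s09,s10,p01,p01	gc01,gc02,gc22,gc23,gc24,gc25,gc44
tp04	apramycin	s04,s08,p03	gc14,gc15,gc16,gc21,gc40
tp05	butirosin	s04,p03,p06	gc14,gc15,gc16,gc45
tp06	fortimicin	s19,p03	gc32,gc50
tp07	gentamicin	s04,s07,p03	gc05,gc14,gc15,gc16,gc19,gc20,gc39,gc43
tp08	hygromycinA	s11,s17,s16	gc02,gc06,gc22,gc23,gc24,gc26,gc37,gc43
tp09	istamycin	s19,p03	gc05,gc33,gc45
tp10	kanamycin	s04,s06,p03	gc05,gc12,gc13,gc15,gc16,gc35,gc37
tp11	lividomycin	s04,s05,s13,p01,p06	gc05,gc12,gc14,gc15,gc16,gc17,gc35,gc45,gc50
tp12	kasugamycin	s14,p01	gc01,gc12,gc28,gc39
tp13	neomycin	s04,s05,p03,p06	gc05,gc12,gc14,gc15,gc16,gc17,gc35,gc44,gc48
tp14	paromomycin	s04,s13,p03,p06	gc05,gc14,gc15,gc16,gc17,gc40,gc47
tp15	ribostamycin	s04,p03,p06	gc05,gc14,gc37,gc41
tp16	sisomicin	s04,s12,p03	gc05,gc12,gc14,gc16,gc17,gc39,gc40
tp17	spectinomycin	s11,s15	gc02,gc05,gc06,gc26,gc27,gc40
tp18	tobramycin	s04,s06,p03	gc01,gc12,gc13,gc14,gc15,gc18,gc44,gc50
tp19	streptomycin	s01,s02,s03	gc01,gc05,gc06,gc07,gc08,gc09,gc10,gc11,gc40,gc44
tp20	dhurrin	p01,s20	gc35,gc45,gc46
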