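# glycomine-kb v1 gene classes
# monomer_roles / modification_roles: comma-separated target ids (may be empty)
id	name	hmm_ref	monomer_roles	modification_roles
gc01	NDP-glucose synthase	HMM_gc01	s02,s03,s06,s10,s14,s15,s17,s18
gc02	NDP-glucose 4,6-dehydratase	HMM_gc02	s02,s10,s14,s15,s17,s18
gc03	myo-inositol-phosphate synthase	HMM_gc03	s01
gc04	inositol amidinotransferase	HMM_gc04	s01
gc05	cyclitol aminotransferase	HMM_gc05	s01,s04,s11,s19
gc06	inositol dehydrogenase	HMM_gc06	s01,s11
gc07	cyclitol phosphate phosphatase	HMM_gc07	s01
gc08	dihydrostreptose synthase	HMM_gc08	s02
gc09	NDP-hexose 3,5-epimerase	HMM_gc09	s02,s15
gc10	NDP-hexose reductase	HMM_gc10	s01,s02
gc11	hexosamine N-methyltransferase	HMM_gc11	s03
gc12	NDP-hexose aminotransferase	HMM_gc12	s03,s05,s06,s08,s10,s12,s13,s14
gc13	NDP-hexose 3-dehydrogenase	HMM_gc13	s03,s06
gc14	2-deoxy-scyllo-inosose synthase	HMM_gc14	s04
gc15	2-deoxy-scyllo-inosose aminotransferase	HMM_gc15	s04
gc16	2-deoxystreptamine dehydrogenase	HMM_gc16	s04
gc17	hexose 6-aminotransferase	HMM_gc17	s05,s08,s12,s13
gc18	kanosamine 3-oxidase	HMM_gc18	s06
gc19	hexosamine 3-N-methyltransferase	HMM_gc19	s07
gc20	NDP-hexose 4-C-methyltransferase	HMM_gc20	s07,s18
gc21	NDP-hexose 3,4-dehydratase	HMM_gc21	s08,s12
gc22	sedoheptulose-7-phosphate cyclase	HMM_gc22	s09,s16
gc23	cyclitol kinase	HMM_gc23	s09,s16
gc24	cyclitol oxidoreductase	HMM_gc24	s09,s16
gc25	NDP-hexose 4-aminotransferase	HMM_gc25	s10
gc26	aminocyclitol N,N-dimethyltransferase	HMM_gc26	s11
gc27	actinamine dehydrogenase	HMM_gc27	s11
gc28	NDP-hexose 2,3-dehydratase	HMM_gc28	s14
gc29	NDP-hexose formyltransferase	HMM_gc29	s15
gc30	NDP-hexose 4-O-methyltransferase	HMM_gc30	s17
gc31	NDP-hexose 3-C-methyltransferase	HMM_gc31	s18
gc32	fortamine O-methyltransferase	HMM_gc32	s19
gc33	fortamine N-methyltransferase	HMM_gc33	s19
gc34	UDP-glucose 6-dehydrogenase	HMM_gc34	s20
gc35	hexose-1-phosphate nucleotidyltransferase	HMM_gc35	s05,s06,s13,s20
gc36	tailoring O-methyltransferase	HMM_gc36		mr01,mr02,mr03,mr30,mr40
gc37	tailoring N-methyltransferase	HMM_gc37		mr04,mr05,mr31
gc38	tailoring C-methyltransferase	HMM_gc38		mr06,mr07,mr37,mr48
gc39	O-acetyltransferase	HMM_gc39		mr08,mr09
gc40	N-acyltransferase	HMM_gc40		mr10,mr32,mr33
gc41	O-carbamoyltransferase	HMM_gc41		mr11,mr12,mr41,mr43
gc42	O-phosphotransferase	HMM_gc42		mr13,mr14
gc43	sulfotransferase	HMM_gc43		mr15,mr42
gc44	tailoring aminotransferase	HMM_gc44		mr16,mr17,mr34,mr41,mr47
gc45	tailoring oxidoreductase	HMM_gc45		mr18,mr19,mr26,mr28,mr29,mr34,mr35,mr38,mr47
gc46	tailoring ketoreductase	HMM_gc46		mr20,mr39
gc47	tailoring dehydratase	HMM_gc47		mr21,mr22,mr46,mr49
gc48	radical SAM deoxygenase	HMM_gc48		mr23,mr27,mr46
gc49	tailoring amidinotransferase	HMM_gc49		mr24,mr45
gc50	tailoring monooxygenase	HMM_gc50		mr25,mr26,mr36,mr44,mr48
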