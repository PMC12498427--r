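# glycomine-kb v1 monomers
# reactive_groups: semicolon-separated type:atom_index, atom indices 1-based
# in SMILES atom-appearance order (heavy atoms only)
id	name	smiles	reactive_groups	required_gene_classes	is_primary
p01	D-glucose	OCC1OC(O)C(O)C(O)C1O	activated-anomeric:6;hydroxyl:1;hydroxyl:8;hydroxyl:12		1
p02	D-mannose	OCC1OC(O)C(O)C(O)C1O	activated-anomeric:6;hydroxyl:1;hydroxyl:8;hydroxyl:12		1
p03	D-glucosamine	OCC1OC(O)C(N)C(O)C1O	activated-anomeric:6;hydroxyl:1;amine:8;hydroxyl:12		1
p04	N-acetylglucosamine	OCC1OC(O)C(NC(C)=O)C(O)C1O	activated-anomeric:6;hydroxyl:1;hydroxyl:13		1
p05	D-xylose	OC1COC(O)C(O)C1O	activated-anomeric:6;hydroxyl:1;hydroxyl:8		1
p06	D-ribose	OCC1OC(O)C(O)C1O	activated-anomeric:6;hydroxyl:1;hydroxyl:8;hydroxyl:10		1
s01	streptidine	NC(=N)NC1C(O)C(O)C(NC(=N)N)C(O)C1O	hydroxyl:7;hydroxyl:9;hydroxyl:16;hydroxyl:18	gc03,gc04,gc05,gc06,gc07,gc10	0
s02	dihydrostreptose	CC1OC(O)C(O)C1(O)CO	activated-anomeric:5;hydroxyl:7;hydroxyl:11	gc01,gc02,gc08,gc09,gc10	0
s03	N-methyl-L-glucosamine	OCC1OC(O)C(NC)C(O)C1O	activated-anomeric:6;hydroxyl:1;amine:8;hydroxyl:11	gc01,gc11,gc12,gc13	0
s04	2-deoxystreptamine	NC1CC(N)C(O)C(O)C1O	amine:1;hydroxyl:7;hydroxyl:9;hydroxyl:11	gc05,gc14,gc15,gc16	0
s05	neosamine C	NCC1OC(O)C(N)C(O)C1O	activated-anomeric:6;amine:1;hydroxyl:10	gc12,gc17,gc35	0
s06	kanosamine	OCC1OC(O)C(O)C(N)C1O	activated-anomeric:6;hydroxyl:1;amine:10	gc01,gc12,gc13,gc18,gc35	0
s07	garosamine	CNC1C(O)C(O)OCC1(C)O	activated-anomeric:7;hydroxyl:5;hydroxyl:12	gc19,gc20	0
s08	purpurosamine	NCC1CCC(N)C(O)O1	activated-anomeric:9;amine:1;amine:7	gc12,gc17,gc21	0
s09	valienamine	NC1C=C(CO)C(O)C(O)C1O	amine:1;hydroxyl:6;hydroxyl:8	gc22,gc23,gc24	0
s10	4-amino-4,6-dideoxy-D-glucose	CC1OC(O)C(O)C(O)C1N	activated-anomeric:5;hydroxyl:9;amine:11	gc01,gc02,gc12,gc25	0
s11	actinamine	CNC1C(O)C(O)C(NC)C(O)C1O	hydroxyl:5;hydroxyl:7;hydroxyl:12	gc05,gc06,gc26,gc27	0
s12	sisosamine	NCC1=CCC(N)C(O)O1	activated-anomeric:9;amine:1;amine:7	gc12,gc17,gc21	0
s13	6-amino-6-deoxy-D-glucose	NCC1OC(O)C(O)C(O)C1O	activated-anomeric:6;amine:1;hydroxyl:8	gc12,gc17,gc35	0
s14	kasugamine	CC1OC(O)C(N)CC1N	activated-anomeric:5;amine:7;amine:10	gc01,gc02,gc12,gc28	0
s15	streptose	CC1OC(O)C(O)C1(O)C=O	activated-anomeric:5;hydroxyl:7;ketone:10	gc01,gc02,gc09,gc29	0
s16	valienone	O=C1C=C(CO)C(O)C(O)C1O	ketone:2;hydroxyl:6;hydroxyl:8	gc22,gc23,gc24	0
s17	4-O-methyl-D-fucose	CC1OC(O)C(O)C(O)C1OC	activated-anomeric:5;hydroxyl:7;hydroxyl:9	gc01,gc02,gc30	0
s18	evalose	CC1OC(O)C(O)C(C)(O)C1O	activated-anomeric:5;hydroxyl:7;hydroxyl:12	gc01,gc02,gc20,gc31	0
s19	fortamine	CNC1C(O)C(OC)C(N)C(O)C1O	hydroxyl:5;amine:10;hydroxyl:12	gc05,gc32,gc33	0
s20	D-glucuronic acid	OC1OC(C(=O)O)C(O)C(O)C1O	activated-anomeric:1;carboxyl:5;hydroxyl:9;hydroxyl:13	gc34,gc35	0
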