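# glycomine-kb v1 postassembly modifications
# commands: semicolon-separated program over add/remove/connect/disconnect;
# atom indices are stable ids, 1-based in motif SMILES appearance order,
# added atoms continue the numbering. Multi-enzyme rules join gene-class
# ids with '+'. mass_delta derived from elemental composition accounting.
id	name	enzyme_gene_classes	motif_smiles	commands	mass_delta
mr01	O-methylation (hydroxyl)	gc36	CO	add 3 C;connect 2 3 1	14.01565006
mr02	O-methylation (secondary alcohol)	gc36	CC(O)C	add 5 C;connect 3 5 1	14.01565006
mr03	O-methylation (primary alcohol, diol context)	gc36	OCCO	add 5 C;connect 1 5 1	14.01565006
mr04	N-methylation (amine)	gc37	CN	add 3 C;connect 2 3 1	14.01565006
mr05	N-methylation (secondary carbon amine)	gc37	CC(N)C	add 5 C;connect 3 5 1	14.01565006
mr06	C-methylation (carbinol carbon)	gc38	CCO	add 4 C;connect 2 4 1	14.01565006
mr07	C-methylation (aminated carbon)	gc38	CCN	add 4 C;connect 2 4 1	14.01565006
mr08	O-acetylation (hydroxyl)	gc39	CO	add 3 C;add 4 C;add 5 O;connect 2 3 1;connect 3 4 1;connect 3 5 2	42.01056468
mr09	O-acetylation (primary alcohol)	gc39	OCC	add 4 C;add 5 C;add 6 O;connect 1 4 1;connect 4 5 1;connect 4 6 2	42.01056468
mr10	N-acetylation	gc40	CN	add 3 C;add 4 C;add 5 O;connect 2 3 1;connect 3 4 1;connect 3 5 2	42.01056468
mr11	O-carbamoylation (hydroxyl)	gc41	CO	add 3 C;add 4 O;add 5 N;connect 2 3 1;connect 3 4 2;connect 3 5 1	43.00581366
mr12	O-carbamoylation (primary alcohol)	gc41	OCC	add 4 C;add 5 O;add 6 N;connect 1 4 1;connect 4 5 2;connect 4 6 1	43.00581366
mr13	O-phosphorylation (hydroxyl)	gc42	CO	add 3 P;add 4 O;add 5 O;add 6 O;connect 2 3 1;connect 3 4 2;connect 3 5 1;connect 3 6 1	79.96633053
mr14	O-phosphorylation (primary alcohol)	gc42	OCC	add 4 P;add 5 O;add 6 O;add 7 O;connect 1 4 1;connect 4 5 2;connect 4 6 1;connect 4 7 1	79.96633053
mr15	O-sulfation	gc43	CO	add 3 S;add 4 O;add 5 O;add 6 O;connect 2 3 1;connect 3 4 2;connect 3 5 2;connect 3 6 1	79.95681487
mr16	transamination (ketone to amine)	gc44	C=O	disconnect 1 2;remove 2;add 3 N;add 4 H;add 5 H;connect 3 4 1;connect 3 5 1;connect 1 3 1	1.03163448
mr17	transamination (chain ketone)	gc44	CC(=O)C	disconnect 2 3;remove 3;add 5 N;connect 2 5 1	1.03163448
mr18	oxidation (hydroxyl to ketone)	gc45	CO	connect 1 2 2	-2.01565006
mr19	oxidation (secondary alcohol)	gc45	CC(O)C	connect 2 3 2	-2.01565006
mr20	ketoreduction	gc46	C=O	connect 1 2 1	2.01565006
mr21	dehydration (vicinal diol to ketone)	gc47	C(O)CO	disconnect 1 2;remove 2;disconnect 3 4;connect 1 4 2	-18.01056468
mr22	dehydration (alcohol to alkene)	gc47	CCO	disconnect 2 3;remove 3;connect 1 2 2	-18.01056468
mr23	deoxygenation	gc48	CO	disconnect 1 2;remove 2	-15.99491462
mr24	amidination (amine to guanidine)	gc49	CN	add 3 C;add 4 N;add 5 N;connect 2 3 1;connect 3 4 2;connect 3 5 1	42.02179807
mr25	hydroxylation (C-H)	gc50	CC	add 3 O;connect 1 3 1	15.99491462
mr26	oxidative carboxylation (primary alcohol)	gc45+gc50	OCC	add 4 O;connect 2 4 2	13.97926456
mr27	deamination	gc48	CN	disconnect 1 2;remove 2	-15.01089903
mr28	decarboxylation	gc45	CC(=O)O	disconnect 1 2;disconnect 2 3;disconnect 2 4;remove 2;remove 3;remove 4	-43.98982924
mr29	epimerization (achiral identity)	gc45	CO		0
mr30	O-methylation (anomeric hydroxyl)	gc36	OC(O)C	add 5 C;connect 1 5 1	14.01565006
mr31	N-ethylation	gc37	CN	add 3 C;add 4 C;connect 2 3 1;connect 3 4 1	28.03130013
mr32	N-formylation	gc40	CN	add 3 C;add 4 O;connect 2 3 1;connect 3 4 2	27.99491462
mr33	N-glycolylation	gc40	CN	add 3 C;add 4 O;add 5 C;add 6 O;connect 2 3 1;connect 3 4 2;connect 3 5 1;connect 5 6 1	58.00547931
mr34	amination (hydroxyl to amine)	gc45+gc44	CO	disconnect 1 2;remove 2;add 3 N;connect 1 3 1	-0.98401559
mr35	oxidation (primary alcohol to aldehyde)	gc45	OCC	connect 1 2 2	-2.01565006
mr36	hydroxylation (carbinol neighbor)	gc50	CCO	add 4 O;connect 1 4 1	15.99491462
mr37	C-methylation (alkyl)	gc38	CC	add 3 C;connect 1 3 1	14.01565006
mr38	dehydrogenation (C-C to C=C)	gc45	CC	connect 1 2 2	-2.01565006
mr39	enoyl reduction	gc46	C=C	connect 1 2 1	2.01565006
mr40	carboxyl O-methylation (methyl ester)	gc36	CC(=O)O	add 5 C;connect 4 5 1	14.01565006
mr41	carboxamide formation	gc44+gc41	CC(=O)O	disconnect 2 4;remove 4;add 5 N;connect 2 5 1	-0.98401559
mr42	N-sulfation	gc43	CN	add 3 S;add 4 O;add 5 O;add 6 O;connect 2 3 1;connect 3 4 2;connect 3 5 2;connect 3 6 1	79.95681487
mr43	N-carbamoylation	gc41	CN	add 3 C;add 4 O;add 5 N;connect 2 3 1;connect 3 4 2;connect 3 5 1	43.00581366
mr44	N-hydroxylation	gc50	CN	add 3 O;connect 2 3 1	15.99491462
mr45	amidination (secondary amine)	gc49	CC(N)C	add 5 C;add 6 N;add 7 N;connect 3 5 1;connect 5 6 2;connect 5 7 1	42.02179807
mr46	vicinal dideoxygenation	gc48+gc47	OCCO	disconnect 1 2;remove 1;disconnect 3 4;remove 4	-31.98982924
mr47	oxidative deamination (amine to ketone)	gc45+gc44	CN	disconnect 1 2;remove 2;add 3 O;connect 1 3 2	-1.03163448
mr48	C-hydroxymethylation	gc38+gc50	CC	add 3 C;add 4 O;connect 1 3 1;connect 3 4 1	30.01056468
mr49	4,6-dehydration (terminal diol to ketone)	gc47	OCCO	disconnect 1 2;remove 1;disconnect 3 4;connect 3 4 2	-18.01056468
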