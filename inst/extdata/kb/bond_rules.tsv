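# glycomine-kb v1 bond rules
# three fundamental rule families; ribosylation is glycosylation with a
# ribose donor. The activated-anomeric group is the anomeric hydroxyl
# oxygen standing in for the NDP/GDP/UDP/dTDP activating group; it leaves
# on bond formation, so every family condenses with net loss of H2O.
id	reaction_name	donor_group_type	acceptor_group_type	leaving_composition
b1	glycosylation	activated-anomeric	hydroxyl	H2O
b2	glycosylation	activated-anomeric	amine	H2O
b3	dehydration	hydroxyl	hydroxyl	H2O
b4	dehydration	hydroxyl	amine	H2O
b5	amidation	carboxyl	amine	H2O
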