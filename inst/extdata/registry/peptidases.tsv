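# Signal peptidases and the domains that mark their substrates' signal
# peptides or mature regions.
accession	component	system	component_location	role	ambiguous	comment
pfam01252	LspA (signal peptidase II)	Sec	IM	peptidase	FALSE	Merops A08; also cleaves Tat lipoprotein substrates
pfam00717	LepB (signal peptidase I)	Sec	IM	peptidase	FALSE	Merops S26A; source also lists this accession for TraF (IncP, S26C)
pfam07963	prepilin leader (PilD-cleaved)	T2SS	IM	substrate_signature	FALSE	Merops A24A peptidase PilD; GspK/PilX/PilW escape this domain
TIGR02532	type IV pilin	T2SS	IM	substrate_signature	FALSE
pfam02501	Gsp substrate domain	T2aSS	IM	substrate_signature	FALSE
pfam03934	GspK	T2aSS	IM	substrate_signature	FALSE
pfam08334	Gsp substrate domain	T2aSS	IM	substrate_signature	FALSE
pfam12019	Gsp substrate domain	T2aSS	IM	substrate_signature	FALSE
TIGR01409	Tat signal peptide	Tat	IM	substrate_signature	FALSE
pfam10518	Tat signal peptide	Tat	IM	substrate_signature	FALSE
TIGR01847	bacteriocin twin-glycine leader (C39-cleaved)	T1SS	EXTRA	substrate_signature	FALSE	peptidase activity encoded in the T1SS permease N-terminus
pfam01721	class I/II bacteriocin / microcin	T1SS	EXTRA	substrate_signature	FALSE
pfam10439	class I/II bacteriocin / microcin	T1SS	EXTRA	substrate_signature	FALSE
TIGR02758	TraA pilin (IncJ)	T4bSS	IM	substrate_signature	FALSE	cleaved by TraF (S26A)
pfam04956	TrbC pilin (IncP)	T4bSS	IM	substrate_signature	FALSE	cleaved by TraF (S26C)
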