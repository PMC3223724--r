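# Universally conserved core components of export / sorting systems, plus the
# membrane-fusion and permease domains that identify TolC-dependent T1SS.
# component_location values on the controlled vocabulary; CYT = cytoplasmic
# (inner-membrane associated).
accession	component	system	component_location	role	ambiguous	comment
TIGR00967	SecY	Sec	IM	core_machinery	FALSE
pfam00344	SecY	Sec	IM	core_machinery	FALSE
TIGR00964	SecE	Sec	IM	core_machinery	FALSE
pfam00584	SecE	Sec	IM	core_machinery	FALSE
TIGR00810	SecG	Sec	IM	core_machinery	FALSE
pfam03840	SecG	Sec	IM	core_machinery	FALSE
TIGR01411	TatA	Tat	IM	core_machinery	FALSE
TIGR01410	TatB	Tat	IM	core_machinery	FALSE
pfam02416	TatA/TatB	Tat	IM	core_machinery	FALSE	shared domain of TatA and TatB
TIGR00945	TatC	Tat	IM	core_machinery	FALSE
pfam00902	TatC	Tat	IM	core_machinery	FALSE
TIGR00548	LolB	Lol	LIPO_OM	core_machinery	FALSE	source table also lists this accession for LolC (IM)
pfam03550	LolB	Lol	LIPO_OM	core_machinery	FALSE	source table also lists this accession for LolC (IM)
TIGR00547	LolA	Lol	PERI	core_machinery	FALSE	beta/gamma proteobacteria; periplasmic chaperone
pfam03548	LolA	Lol	PERI	core_machinery	FALSE	beta/gamma proteobacteria; periplasmic chaperone
TIGR00221	LolD	Lol	CYT	core_machinery	FALSE	cytoplasmic, inner-membrane associated ATPase
TIGR02212	LolE	Lol	IM	core_machinery	FALSE
TIGR03303	BamA	Bam	OM	core_machinery	FALSE
TIGR03300	BamB	Bam	LIPO_OM	core_machinery	FALSE
TIGR03302	BamC	Bam	LIPO_OM	core_machinery	FALSE
pfam06804	BamD	Bam	LIPO_OM	core_machinery	FALSE
pfam04355	BamE	Bam	LIPO_OM	core_machinery	FALSE
TIGR01843	HlyD-family membrane fusion protein	T1SS	IM	core_machinery	FALSE	identifies TolC-dependent T1SS loci
TIGR01842	T1SS permease (PrtD family)	T1SS	IM	core_machinery	FALSE	identifies TolC-dependent T1SS loci
TIGR01846	T1SS permease (HlyB family)	T1SS	IM	core_machinery	FALSE	identifies TolC-dependent T1SS loci
TIGR03375	T1SS permease (LssB family)	T1SS	IM	core_machinery	FALSE	identifies TolC-dependent T1SS loci
pfam0341	bacteriocin exporter permease/C39 peptidase	T1SS	IM	core_machinery	TRUE	accession truncated in source; stored verbatim
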