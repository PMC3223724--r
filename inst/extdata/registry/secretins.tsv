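# Secretin / usher domains that anchor secretion-system loci.
# component_location values: OM, LIPO_OM ("OM lipoprotein"), or mixed.
accession	descriptor	system	proteins	component_location	role	ambiguous
pfam02321	Outer membrane efflux protein	T1SS	AggA	OM	secretin	FALSE
TIGR01844	type I secretion outer membrane protein, TolC family	T1SS	TolC,AggA	OM	secretin	FALSE
TIGR02519	pilus (MSHA type) biogenesis protein MshL	T2bSS	MshL	LIPO_OM	secretin	FALSE
pfam07655	Secretin N-terminal domain	T2bSS	MshL	LIPO_OM	secretin	FALSE
TIGR02515	type IV pilus secretin (or competence protein) PilQ	T2bSS	PilQ	LIPO_OM	secretin	FALSE
pfam00263	Bacterial type II and III secretion system protein	T2a-cSS,T3aSS	GspD,PilQ,MshL,YscC,RcpA,SspD	mixed	secretin	FALSE
pfam03958	Bacterial type II/III secretion system short domain	T2a-bSS,T3aSS	GspD,PilQ,YscC	mixed	secretin	FALSE
pfam02107	Flagellar L-ring protein	T3bSS	FlgH	LIPO_OM	secretin	FALSE
pfam03524	Conjugal transfer protein	T4bSS	TrbG	OM	secretin	FALSE
pfam03895	YadA-like C-terminal region	T5cSS		mixed	secretin	FALSE
pfam03797	Autotransporter beta-domain	T5aSS		mixed	secretin	FALSE
pfam06586	TraK protein	T4bSS	TraK,TrhK	OM	secretin	FALSE
pfam07660	Secretin and TonB N terminus short domain	T2bSS	PilQ,MshL	LIPO_OM	secretin	FALSE
TIGR02516	type III secretion outer membrane pore, YscC/HrcC family	T3aSS	YscC	OM	secretin	FALSE
TIGR02756	type-F conjugative transfer system secretin TraK	T4bSS	TraK	OM	secretin	FALSE
TIGR03352	type VI secretion lipoprotein, VC_A0113 family	T6SS	SciN	LIPO_OM	secretin	FALSE
pfam00577	Fimbrial Usher protein	T7SS	PapC,FimD	OM	secretin	FALSE
pfam03783	Curli production assembly/transport component CsgG	T8SS	CsgG	LIPO_OM	secretin	FALSE
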