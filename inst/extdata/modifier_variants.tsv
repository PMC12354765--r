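rsid	locus	effect_allele	klass
rs72973581	ABCA7	A	protective
rs466433	APP	G	protective
rs364048	APP	C	protective
rs13116075	NOCT	G	protective
rs11218343	SORL1	C	protective
rs12881735	SLC24A4	C	protective
rs6024870	CASS4	A	protective
rs11762262	EPHA1	A	protective
rs59685680	SPPL2A	G	protective
rs63750847	APP	T	protective
rs72824905	PLCG2	G	protective
rs10423769	19q13.31	A	resilient
rs449647	APOE	T	resilient
rs140926439	FN1	T	resilient
rs116558455	FN1	A	resilient
rs201731543	RELN	C	resilient
rs11556505	TOMM40	T	resilient
rs142787485	RAB10	G	resilient
rs2732703	LRRC37A	G	resilient
rs9749589	NFIC	A	resilient
rs121918393	APOE	A	resilient
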