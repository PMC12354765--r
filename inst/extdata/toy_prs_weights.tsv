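# synthetic PRS weight panel (not a published GWAS); betas are per effect allele
chrom	pos	effect_allele	other_allele	beta
chr19	44908684	C	T	1.20
chr19	44908822	C	T	0.45
chr2	127090354	A	G	0.16
chr4	139322422	G	A	-0.07
chr6	32583357	T	C	0.21
chr6	41161469	T	C	0.29
chr7	100374211	A	G	0.10
chr8	27362470	T	C	-0.12
chr11	60254475	C	T	0.13
chr11	86156833	G	A	-0.11
chr11	121564878	C	T	0.08
chr14	92472511	C	G	-0.09
chr15	50709583	G	A	-0.06
chr16	81908423	A	C	0.05
chr17	5233752	G	A	0.07
chr19	1063443	G	T	0.14
chr19	45221584	A	G	0.17
chr20	56423488	A	G	-0.08
chr21	26775872	C	T	0.06
chr1	207577223	G	A	-0.14
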