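gene	chrom	start	end
APP	chr21	25880550	26171128
PSEN1	chr14	73136418	73223691
PSEN2	chr1	226870184	226903829
TREM2	chr6	41158506	41163186
MAPT	chr17	45894382	46028334
GRN	chr17	44345246	44353106
GBA1	chr1	155234452	155244699
SNCA	chr4	89724099	89838315
TBK1	chr12	64452120	64502114
TARDBP	chr1	11012654	11030528
APOE	chr19	44905791	44909393
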