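abbreviation	name	phylum_order	growth_temp	gc_percent	srna_gene_count
Neq	Nanoarchaeum equitans	Nanoarchaeota	80-100 C	31.6	26
Iho	Ignicoccus hospitalis	Crenarchaeota/Desulfurococcales	80-100 C	56.5	128
Mma	Methanococcus maripaludis C5	Euryarchaeota/Methanococcales	35-40 C	33.0	7
Mka	Methanopyrus kandleri	Euryarchaeota/Methanopyrales	84-110 C	61.2	127
Pca	Pyrobaculum calidifontis	Crenarchaeota/Thermoproteales	90-100 C	57.2	88
Sac	Sulfolobus acidocaldarius	Crenarchaeota/Sulfolobales	67-80 C	36.7	61
Tte	Thermoproteus tenax	Crenarchaeota/Thermoproteales	70-97 C	55.1	52
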