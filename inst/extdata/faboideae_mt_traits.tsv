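# Genome traits of eight Faboideae mitochondrial genomes (repeat totals use
# a >19 bp length and >80% identity filter). VraI/VraII share one column in
# the source annotation; they are reported here under one id.
genome	accession	size_bp	gc_pct	genes	trnas	rrnas	protein_genes	repeats_bp	genes_bp	protein_exon_bp	intron_bp
Sja	MG757109	484916	45.4	53	18	3	32	19601	64347	29501	28035
Mtr	KT971339	271618	45.4	52	17	3	32	5406	60179	28435	25209
Lja	JN872551	380861	45.4	51	17	3	31	57409	67655	31195	29940
Mpi	JN872550	425718	45.0	54	18	3	33	58847	76077	34012	35119
Gma	JX463295	402558	45.0	52	17	3	32	72873	73265	34133	32553
Van	AP012599	404466	45.2	50	16	3	31	13451	65756	28918	30398
Vra	HM367685	401262	45.1	50	16	3	31	7925	66095	28879	30772
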