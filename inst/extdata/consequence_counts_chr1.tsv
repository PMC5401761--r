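category	snp	novel_snp	indel	novel_indel
splice_donor_variant	29	9	2	0
splice_acceptor_variant	11	0	4	0
stop_gained	19	8	1	1
frameshift_variant	0	0	22	7
stop_lost	5	1	1	0
start_lost	11	3	2	0
missense_variant	2378	486	0	0
inframe_insertion	0	0	28	2
inframe_deletion	0	0	26	2
splice_region_variant	1117	63	244	18
synonymous_variant	4238	281	0	0
stop_retained_variant	3	0	0	0
coding_sequence_variant	1	0	1	0
mature_miRNA_variant	4	2	2	0
5_prime_UTR_variant	1210	86	198	31
3_prime_UTR_variant	6563	484	1617	191
non_coding_transcript_exon_variant	11955	640	2140	290
intron_variant	575013	36838	139815	21458
NMD_transcript_variant	42052	2609	10291	1372
non_coding_transcript_variant	143110	8770	32985	5190
upstream_gene_variant	96888	8357	24321	3992
downstream_gene_variant	93184	5752	23557	3390
intergenic_variant	224557	13198	48568	8312
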