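rank	term	impact
1	transcript_ablation	HIGH
2	splice_acceptor_variant	HIGH
3	splice_donor_variant	HIGH
4	stop_gained	HIGH
5	frameshift_variant	HIGH
6	stop_lost	HIGH
7	start_lost	HIGH
8	transcript_amplification	HIGH
9	inframe_insertion	MODERATE
10	inframe_deletion	MODERATE
11	missense_variant	MODERATE
12	protein_altering_variant	MODERATE
13	splice_region_variant	LOW
14	incomplete_terminal_codon_variant	LOW
15	start_retained_variant	LOW
16	stop_retained_variant	LOW
17	synonymous_variant	LOW
18	coding_sequence_variant	MODIFIER
19	mature_miRNA_variant	MODIFIER
20	5_prime_UTR_variant	MODIFIER
21	3_prime_UTR_variant	MODIFIER
22	non_coding_transcript_exon_variant	MODIFIER
23	intron_variant	MODIFIER
24	NMD_transcript_variant	MODIFIER
25	non_coding_transcript_variant	MODIFIER
26	upstream_gene_variant	MODIFIER
27	downstream_gene_variant	MODIFIER
28	TFBS_ablation	MODIFIER
29	TFBS_amplification	MODIFIER
30	TF_binding_site_variant	MODIFIER
31	regulatory_region_variant	MODIFIER
32	intergenic_variant	MODIFIER
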