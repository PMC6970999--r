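gt_proband	gt_mother	gt_father	modes
0/0	0/0	0/0
0/0	0/0	0/1
0/0	0/0	1/1
0/0	0/1	0/0
0/0	0/1	0/1
0/0	0/1	1/1
0/0	1/1	0/0
0/0	1/1	0/1
0/0	1/1	1/1
0/1	0/0	0/0	DE_NOVO
0/1	0/0	0/1
0/1	0/0	1/1
0/1	0/1	0/0
0/1	0/1	0/1
0/1	0/1	1/1
0/1	1/1	0/0
0/1	1/1	0/1
0/1	1/1	1/1
1/1	0/0	0/0	DE_NOVO
1/1	0/0	0/1
1/1	0/0	1/1
1/1	0/1	0/0
1/1	0/1	0/1	AUTOSOMAL_RECESSIVE
1/1	0/1	1/1
1/1	1/1	0/0
1/1	1/1	0/1
1/1	1/1	1/1
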