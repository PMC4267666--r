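section	category	snv_total	snv_avg	indel_total	indel_avg
A	total	12732271	3302407	1916622	453821
A	germline	10010429	3177173	1597810	429846
A	somatic	2721842	125234	318812	23975
A	genic	892941	39695	118268	8516
A	upstream	11796	551	2049	159
A	utr	24902	1086	13	0.8
A	cds	16354	687	573	37
A	synonymous	4505	188	NA	NA
A	non_synonymous	11849	499	NA	NA
A	splice_site	346	14	39	3
A	intronic_others	839543	37357	115594	8315
A	intergenic	1828901	85539	200544	15459
B	regulatory	NA	11413	NA	2160
B	promoter	NA	2187	NA	497
B	promoter_diff_H3K4me3	NA	181	NA	36
B	enhancer_H3K4me1	NA	7543	NA	1305
B	enhancer_diff_H3K4me1	NA	3163	NA	524
B	enhancer_H3K27ac	NA	5549	NA	1006
B	enhancer_diff_H3K27ac	NA	2647	NA	465
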