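species	assembly_mbp	pct_determined	n_auto	n_ogs	n_auto_sub	n_man_sub	n_man_add	median_transcript_length_auto_sub	median_transcript_length_man_sub	median_protein_length_auto_sub	median_protein_length_man_sub	median_exon_count_auto_sub	median_exon_count_man_sub
Anoplophora_glabripennis	707.7	85.1	22253	22035	749	770	216	6183	5789.5	358	389	4	4
Leptinotarsa_decemlineata	1170.2	58.0	24732	24671	972	933	98	8562.5	9280	255	300	4	4
Athalia_rosae	163.8	95.7	11956	11894	805	825	50	4340	3208	445	423	6	5
Orussus_abietinus	201.2	92.7	10966	10959	659	670	30	5200	3996	430	419	5	5.5
Cimex_lectularius	650.5	79.0	14085	13953	795	778	221	4362	4360	358	372.5	5	5
Oncopeltus_fasciatus	1098.7	70.4	19587	19615	1013	945	161	9324	11244	257	320	4	4
Frankliniella_occidentalis	415.8	63.4	18021	17553	1118	1127	381	5001.5	4064	419.5	419	6	6
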