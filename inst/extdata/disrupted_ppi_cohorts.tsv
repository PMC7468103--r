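normal_tissue	cancer_type	total_disrupted_ppi	n_samples	mean_disrupted_ppi_printed
Uterus	Uterus-AdenoCA	3792	44	86.2
Esophagus	Eso-AdenoCA	316	7	45.1
CervixUteri	Cervix-SCC	794	18	44.1
Colon	ColoRect-AdenoCA	1651	51	32.4
Bladder	Bladder-TCC	637	23	27.7
Ovary	Ovary-AdenoCA	2788	110	25.3
Kidney	Kidney-RCC	2328	117	19.9
Pancreas	Panc-AdenoCA	1059	75	14.1
Liver	Biliary-AdenoCA	243	18	13.5
Muscle	Bone-Leiomyo	415	34	12.2
Thyroid	Thy-AdenoCA	482	47	10.3
Liver	Liver-HCC	841	100	8.4
Breast	Breast-AdenoCA	626	85	7.4
Stomach	Stomach-AdenoCA	169	29	5.8
Blood	Lymph-CLL	360	68	5.3
Lung	Lung-AdenoCA	190	37	5.1
Breast	Breast-LobularCA	30	6	5.0
Kidney	Kidney-ChRCC	194	43	4.5
Lung	Lung-SCC	206	47	4.4
Prostate	Prost-AdenoCA	71	19	3.7
Skin	Skin-Melanoma	74	36	2.1
Blood	Lymph-BNHL	74	103	0.7
Brain	CNS-Oligo	5	18	0.3
Brain	CNS-GBM	6	28	0.2
SalivaryGland	Head-SCC	0	42	0.0
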