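organism	eei_type	coverage	rho	p_value	doubling_time_h	log10_dt	m	r
Staphylococcus aureus	1	62.5	0.66	8.46e-211	0.4	-0.39794	83	25
Shigella flexneri	1	39.4	0.65	4.01e-202	0.5	-0.30103	94	12
Streptococcus pyogenes	1	75.9	0.63	3.60e-141	0.666667	-0.17609	91	26
Lactococcus lactis	1	57.1	0.60	2.58e-128	0.5	-0.30103	76	49
Bacteroides thetaiotaomicron	1	15.9	0.57	2.52e-67	2.7	0.431364	91	20
Listeria monocytogenes	1	16.4	0.57	1.46e-41	0.516667	-0.28679	79	36
Escherichia coli	1	97.40	0.57	0	0.333333	-0.47712	87	30
Bacillus anthracis	4	26.20	0.52	3.42e-102	0.5	-0.30103	77	46
Campylobacter jejuni	2	47.40	0.46	6.48e-42	2.466667	0.39211	67	37
Salmonella typhimurium	1	56.3	0.45	1.79e-126	0.5	-0.30103	85	39
Thermococcus gammatolerans	1	62.2	0.44	3.71e-66	4.5	0.653213	77	32
Legionella pneumophila	4	25.2	0.42	2.50e-05	3.3	0.518514	66	43
Synechocystis sp.	1	37.8	0.40	8.01e-48	5.8	0.763428	53	51
Yersinia pestis	1	29.6	0.40	4.86e-47	1	0	91	26
Desulfovibrio vulgaris	4	27.1	0.39	3.87e-37	2.48	0.394452	79	18
Deinococcus deserti	1	38.5	0.38	6.58e-48	2.6	0.414973	87	28
Bartonella henselae	4	85.7	0.35	1.21e-41	3	0.477121	61	41
Leptospira interrogans	2	66.2	0.35	6.06e-66	8.2	0.913814	59	42
Halobacterium salinarum	4	54.2	0.33	2.00e-02	11	1.041393	36	41
Helicobacter pylori	2	98.8	0.28	1.22e-29	0.833333	-0.07918	51	44
Pseudomonas aeruginosa	3	43.6	0.27	1.37e-42	0.5	-0.30103	83	17
Mycobacterium tuberculosis	4	84	0.26	3.44e-28	14.7	1.167317	36	63
Microcystis aeruginosa	4	79.00	0.24	1.60e-06	46	1.662758	55	46
Mycoplasma pneumoniae	2	60.9	0.14	1.14e-83	8	0.90309	34	54
Acidithiobacillus ferrooxidans	2	41.9	0.12	1.73e-05	5	0.69897	42	47
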