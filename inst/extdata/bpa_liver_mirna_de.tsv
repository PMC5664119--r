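Symbol	baseMean	log2FoldChange	pvalue	padj
dre-miR-430c-3p	25	9.99	6.14e-12	1.33e-9
dre-miR-430b-3p	2007.5	5.75	8.72e-7	9.46e-5
dre-miR-202-5p	156	3.92	5.17e-6	2.80e-4
dre-miR-122	12698	2.60	4.01e-6	2.80e-4
dre-miR-430a-3p	320.75	4.76	8.71e-6	3.78e-4
dre-miR-499-3p	35.5	3.15	4.10e-5	1.48e-3
dre-miR-2189	31.75	-2.34	1.03e-4	2.78e-3
dre-miR-184	703.75	2.06	9.77e-5	2.78e-3
dre-miR-499-5p	43	2.56	2.84e-4	6.84e-3
dre-miR-205-5p	824.5	1.68	1.19e-3	0.026
dre-miR-133a-3p	854.25	2.72	1.89e-3	0.032
dre-miR-724	122.75	2.51	1.95e-3	0.032
dre-miR-458-3p	451	2.02	2.01e-3	0.032
dre-miR-725-3p	355	1.55	2.09e-3	0.032
dre-miR-193a-3p	18.75	1.52	6.64e-3	0.096
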