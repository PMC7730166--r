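gene_symbol	refseq_id	tss_distance	chrom	start	end	length	score	fold_enrichment	pool
Speer5-ps1	NR_001582	1774	chr10	43891861	43892191	330	80.89	31.34	1
Speer5-ps1	NR_001582	1714	chr10	43891774	43892159	385	84.05	54.84	2
Smad9	NM_019483	13586	chr3	54572813	54573365	552	54.2	19.01	1
Smad9	NM_019483	13553	chr3	54572951	54573162	211	177.55	42	2
Brd3	NM_001113573	1760	chr2	27332645	27333262	617	69.33	11.73	1
Brd3	NM_001113573	1685	chr2	27332651	27333106	455	113.72	56.14	3
Arl15	NM_172595	-4637	chr13	114579840	114580317	477	66.57	24	2
Arl15	NM_172595	-4774	chr13	114579814	114580068	254	202.49	84.21	3
Sorbs1	NM_178362	-5037	chr19	40582865	40583513	648	329.19	118.82	2
Sorbs1	NM_178362	-5136	chr19	40582818	40583363	545	54.68	3.63	3
Mcc	NM_001085373	-32144	chr18	44939328	44940056	728	181.78	80.99	2
Mcc	NM_001085373	-31615	chr18	44940046	44940397	351	120.18	50	3
Col4a2	NM_009932	39473	chr8	11352053	11352549	496	77.71	36.56	2
Col4a2	NM_009932	39543	chr8	11352193	11352549	356	77.53	5.34	3
Kcnq1	NM_008434	78040	chr7	150371026	150371370	344	68.98	45.7	2
Kcnq1	NM_008434	78146	chr7	150371043	150371565	522	78.85	20	3
Dgki	NM_001081206	-92744	chr6	37156803	37157662	859	157.22	63.98	2
Dgki	NM_001081206	-93040	chr6	37156803	37157070	267	106.97	15	3
Gng4	NM_001302997	-30831	chr13	13845260	13845728	468	70.97	18.11	1
Gng4	NM_001302997	-30895	chr13	13845144	13845716	572	60.01	27.42	2
Acadm	NM_007382	-22702	chr3	153584775	153585035	260	99.69	45.7	2
Acadm	NM_007382	-22536	chr3	153584852	153585291	439	97.1	10	3
Rabggtb	NM_001163478	8975	chr3	153584775	153585035	260	99.69	45.7	2
Rabggtb	NM_001163478	9141	chr3	153584852	153585291	439	97.1	10	3
Abi3bp	NM_001014422	-20897	chr16	56456644	56457478	834	96.15	30	2
Abi3bp	NM_001014422	-21090	chr16	56456647	56457089	442	63.52	10	3
Edn3	NM_007903	-44835	chr2	174541128	174541718	590	72.63	45.7	2
Edn3	NM_007903	-44498	chr2	174541618	174541903	285	78.44	7.5	3
Nxph1	NM_008751	272432	chr6	9172169	9172731	562	57.91	26.12	1
Nxph1	NM_008751	272487	chr6	9172167	9172843	676	95.92	54.84	2
Atxn1	NM_009124	123721	chr13	45936396	45936882	486	108.42	54.84	2
Atxn1	NM_009124	123568	chr13	45936673	45936912	239	136.16	15	3
Il10ra	NM_008348	-6407	chr9	45070625	45071019	394	80.89	36.57	1
Il10ra	NM_008348	-5195	chr9	45071866	45072203	337	68.59	45	2
Gm15997	NR_045423	-18653	chr5	150321687	150322218	531	60.47	13.46	1
Gm15997	NR_045423	-18668	chr5	150321644	150322230	586	53.95	5	3
Wdr95	NM_029440	-9301	chr5	150321687	150322218	531	60.47	13.46	1
Wdr95	NM_029440	-9316	chr5	150321644	150322230	586	53.95	5	3
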