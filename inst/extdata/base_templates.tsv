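restype	atom	element	x	y	z
DG	P	P	-2.5887	9.6484	-3.9994
DG	OP1	O	-1.1103	9.6501	-4.0532
DG	OP2	O	-3.1067	11.0566	-3.421
DG	O5'	O	-3.0901	8.4563	-3.0407
DG	C5'	C	-2.5368	8.7064	-1.748
DG	C4'	C	-2.9766	7.6041	-0.7828
DG	O4'	O	-2.4121	6.3298	-1.1678
DG	C3'	C	-2.39	7.8492	0.6308
DG	O3'	O	-3.2335	8.7192	1.3895
DG	C2'	C	-2.3841	6.4234	1.2311
DG	C1'	C	-2.4288	5.4958	0.0019
DG	N9	N	-1.2618	4.6119	0.0009
DG	C8	C	0.0451	5.0022	0.0009
DG	N7	N	0.8187	3.9554	-0.0003
DG	C5	C	0.0564	2.8347	-0.0011
DG	C6	C	0.3415	1.4492	-0.0025
DG	O6	O	1.4927	1.0489	-0.0032
DG	N1	N	-0.6938	0.5818	0.0043
DG	C2	C	-1.9764	1.0402	-0.0009
DG	N2	N	-3.0076	0.1355	-0.0018
DG	N3	N	-2.2543	2.3246	-0.001
DG	C4	C	-1.2824	3.2439	0.0008
DG	H5'	H	-2.8888	9.6708	-1.3833
DG	H5''	H	-1.4487	8.7178	-1.8136
DG	H4'	H	-4.0636	7.5428	-0.7414
DG	H3'	H	-1.378	8.2494	0.568
DG	H2'	H	-3.2621	6.2694	1.8582
DG	H2''	H	-1.4711	6.2546	1.802
DG	H1'	H	-3.3431	4.9019	0.0203
DG	H8	H	0.3875	6.0271	0.0014
DG	H1	H	-0.5224	-0.3733	0.003
DG	H21	H	-3.9261	0.4469	-0.0013
DG	H22	H	-2.8184	-0.816	-0.0068
DA	P	P	-2.5864	9.5794	-4.0007
DA	OP1	O	-1.1075	9.5819	-4.0524
DA	OP2	O	-3.1059	10.9888	-3.4219
DA	O5'	O	-3.0878	8.3874	-3.0426
DA	C5'	C	-2.536	8.6368	-1.7492
DA	C4'	C	-2.9764	7.534	-0.7846
DA	O4'	O	-2.4111	6.2599	-1.1696
DA	C3'	C	-2.3918	7.7794	0.6293
DA	O3'	O	-3.2357	8.6481	1.3876
DA	C2'	C	-2.3865	6.3538	1.2292
DA	C1'	C	-2.4304	5.4265	-0.0002
DA	N9	N	-1.2612	4.5429	0.0002
DA	C8	C	0.0436	4.933	-0.001
DA	N7	N	0.8198	3.8887	-0.0015
DA	C5	C	0.0641	2.7644	0.005
DA	C6	C	0.3405	1.3872	-0.0013
DA	N6	N	1.6457	0.9271	-0.0025
DA	N1	N	-0.6803	0.5361	-0.0006
DA	C2	C	-1.9276	0.9659	-0.0003
DA	N3	N	-2.2349	2.2454	-0.0
DA	C4	C	-1.281	3.1714	-0.0006
DA	H5'	H	-2.889	9.6017	-1.3842
DA	H5''	H	-1.4489	8.6493	-1.8143
DA	H4'	H	-4.0634	7.4728	-0.745
DA	H3'	H	-1.3801	8.1801	0.5668
DA	H2'	H	-3.2637	6.1998	1.8564
DA	H2''	H	-1.4735	6.1848	1.8018
DA	H1'	H	-3.3438	4.8317	0.0171
DA	H8	H	0.3838	5.9576	-0.0011
DA	H61	H	1.8241	-0.0262	-0.0022
DA	H62	H	2.3826	1.5587	-0.0064
DA	H2	H	-2.7272	0.2397	-0.0007
DC	P	P	-2.6762	9.5377	-4.0047
DC	OP1	O	-1.1977	9.5549	-4.0607
DC	OP2	O	-3.2083	10.9415	-3.4263
DC	O5'	O	-3.1627	8.3406	-3.0433
DC	C5'	C	-2.6101	8.5986	-1.7526
DC	C4'	C	-3.0364	7.4929	-0.7847
DC	O4'	O	-2.4586	6.2255	-1.1685
DC	C3'	C	-2.4508	7.7462	0.6271
DC	O3'	O	-3.3027	8.6074	1.3859
DC	C2'	C	-2.428	6.322	1.2299
DC	C1'	C	-2.4653	5.3918	0.0015
DC	N1	N	-1.2877	4.5209	0.0002
DC	C2	C	-1.4436	3.1856	0.0007
DC	O2	O	-2.5684	2.7127	0.0027
DC	N3	N	-0.3901	2.3704	-0.0001
DC	C4	C	0.8432	2.8571	-0.0014
DC	N4	N	1.9239	2.0059	-0.0015
DC	C5	C	1.0402	4.2529	0.0022
DC	C6	C	-0.04	5.0682	-0.0017
DC	H5'	H	-2.9724	9.5596	-1.3874
DC	H5''	H	-1.523	8.6222	-1.819
DC	H4'	H	-4.123	7.42	-0.7419
DC	H3'	H	-1.444	8.1578	0.5623
DC	H2'	H	-3.3026	6.1598	1.8588
DC	H2''	H	-1.5122	6.1629	1.8002
DC	H1'	H	-3.3728	4.7883	0.0217
DC	H41	H	1.7844	1.0461	-0.0005
DC	H42	H	2.8248	2.3653	-0.0071
DC	H5	H	2.0389	4.6659	0.0008
DC	H6	H	0.0858	6.1404	-0.0033
DT	P	P	0.5293	9.0133	-2.7465
DT	OP1	O	0.8611	8.9227	-4.2074
DT	OP2	O	0.359	10.5161	-2.176
DT	O5'	O	-0.8603	8.3036	-2.3155
DT	C5'	C	-1.2447	8.3441	-0.9516
DT	C4'	C	-2.574	7.6178	-0.793
DT	O4'	O	-2.3742	6.242	-1.1717
DT	C3'	C	-3.0698	7.5958	0.646
DT	O3'	O	-4.49	7.4719	0.6684
DT	C2'	C	-2.4394	6.3419	1.2062
DT	C1'	C	-2.4219	5.417	0.0002
DT	N1	N	-1.298	4.5261	-0.0002
DT	C2	C	-1.474	3.1258	0.0
DT	O2	O	-2.5755	2.5729	-0.0003
DT	N3	N	-0.2907	2.3802	0.0003
DT	C4	C	1.0056	2.8727	-0.0004
DT	O4	O	2.0041	2.158	-0.0014
DT	C5	C	1.1103	4.3562	0.0003
DT	C7	C	2.4756	4.9652	0.0007
DT	C6	C	-0.0212	5.073	-0.0
DT	H5'	H	-0.4729	7.8589	-0.3501
DT	H5''	H	-1.3428	9.3874	-0.6414
DT	H4'	H	-3.3101	8.0509	-1.4773
DT	H3'	H	-2.8118	8.4969	1.2097
DT	H2'	H	-1.4177	6.5589	1.5405
DT	H2''	H	-2.989	5.9026	2.0445
DT	H1'	H	-3.3309	4.8079	-0.0518
DT	H3	H	-0.3929	1.3696	-0.0
DT	H71	H	3.017	4.6515	0.8917
DT	H72	H	2.3948	6.0517	-0.0089
DT	H73	H	3.0215	4.6442	-0.8861
DT	H6	H	0.0107	6.1586	0.0001
DI	P	P	-0.2592	9.5371	-2.8773
DI	OP1	O	0.0551	9.4743	-4.3432
DI	OP2	O	-0.7432	10.9847	-2.3435
DI	O5'	O	-1.4503	8.5544	-2.3907
DI	C5'	C	-1.8084	8.5535	-1.0201
DI	C4'	C	-2.9422	7.5581	-0.8131
DI	O4'	O	-2.4579	6.2477	-1.1745
DI	C3'	C	-3.3942	7.4753	0.6409
DI	O3'	O	-4.7658	7.091	0.6935
DI	C2'	C	-2.5598	6.3442	1.1977
DI	C1'	C	-2.4656	5.4132	-0.0025
DI	N9	N	-1.292	4.5471	-0.0003
DI	C8	C	0.0204	4.9589	-0.0003
DI	N7	N	0.8674	3.9484	0.0003
DI	C5	C	0.0633	2.8457	0.0002
DI	C6	C	0.4442	1.4565	-0.0005
DI	O6	O	1.6057	1.0697	-0.0014
DI	N1	N	-0.687	0.6281	0.0
DI	C2	C	-2.0009	1.1118	0.0002
DI	N3	N	-2.3508	2.3661	0.0004
DI	C4	C	-1.2717	3.1814	0.0011
DI	H5'	H	-0.9427	8.2643	-0.4235
DI	H5''	H	-2.1322	9.5551	-0.7336
DI	H4'	H	-3.7699	7.8054	-1.4866
DI	H3'	H	-3.2872	8.4124	1.1935
DI	H2'	H	-1.5647	6.713	1.4759
DI	H2''	H	-3.0031	5.8439	2.0636
DI	H1'	H	-3.3314	4.7457	-0.0665
DI	H8	H	0.2916	6.0059	-0.0011
DI	H1	H	-0.5457	-0.3777	0.0008
DI	H2	H	-2.7508	0.306	-0.0006
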