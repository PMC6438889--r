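R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
1.47416	-0.45657	0.16749	-0.69249	0.56331	-1.27505	-0.15868	1.74311	0.522	1.82416
1.29309	1.75655	0.22024	2.17377	1.87316	0.43652	0.17899	1.54439	1.61301	-0.45203
-0.46863	-0.7764	-0.7307	-0.49675	-1.11029	-0.63646	0.42867	-2.15977	-3.02447	-3.25345
0.3099	1.22024	0.86	0.42381	0.67892	1.50079	1.58102	1.35617	2.98062	1.78825
-0.91543	-0.28183	-0.51882	-0.26935	2.42738	0.99838	1.3196	1.04576	2.05004	2.33428
-2.19297	-1.4116	-0.79869	-0.16697	-0.54844	-0.16528	-0.65354	-0.49762	-0.97446	-0.7264
-0.58289	-0.84402	-0.70344	-1.67913	-2.33204	-1.1894	-0.57877	-2.52349	-1.70315	-1.63864
-0.32756	-0.48209	1.20952	0.111	-1.02951	-0.26968	-0.36236	-1.31513	-1.25325	-1.76006
1.04701	1.50197	-0.22023	-0.06586	-1.4077	-0.79239	0.00471	-0.37726	-0.01317	-0.63077
-0.76146	1.36203	1.46491	0.09541	-0.66118	-1.45088	-0.49981	-0.89711	-0.38931	-0.84118
-0.55791	-0.61951	-1.94986	-0.51003	1.75594	0.73741	2.18936	0.94462	-0.24027	0.01682
1.77349	-1.27326	-0.81147	-0.94978	-0.26773	1.06718	-0.79092	-0.17305	-0.47308	-0.82986
-1.18873	-0.95512	-0.41069	-1.85537	-0.52419	0.34031	1.14314	0.83856	0.76104	0.23973
0.95988	-0.6209	0.20172	-0.57733	0.83543	0.53813	1.2922	-2.35436	-1.17587	-1.87133
-2.08924	-2.1576	-1.35807	-1.16002	0.69717	0.08633	1.07798	-0.16488	-0.16758	0.46175
-1.99611	-2.06103	-0.69151	-2.13163	1.71089	-0.50025	1.30923	-0.03162	0.3567	0.18979
-2.07971	0.50655	0.69809	0.55346	0.41505	-1.49242	0.65109	0.84038	0.43344	0.18351
0.29872	-0.51416	-0.1009	0.26204	0.77424	1.15885	0.24672	-0.44357	-1.32659	-0.85338
1.53265	-0.72917	-0.10365	0.29875	-0.07222	-1.42008	0.60144	1.20798	2.79046	0.0843
1.11284	2.98231	0.1246	0.07327	0.49379	-1.17096	-0.90404	1.72718	1.71978	0.5925
-0.66761	0.19704	-0.84707	0.70199	-0.16992	0.69969	-0.16282	-0.68402	-1.39707	-1.06492
0.29168	0.49118	1.36257	-0.8896	0.0571	-0.91354	-0.50221	-0.6161	0.13393	-1.09342
-0.11608	0.02442	-1.26377	1.81819	0.01924	0.65632	0.88701	0.2844	-0.84836	-0.37333
1.87172	-1.43289	-0.27962	2.25112	-0.47387	-0.27064	-0.9103	-0.20813	-0.61939	0.50879
0.46162	0.4593	0.01079	-1.94128	3.45117	0.99515	1.33196	0.42495	-1.65858	-3.50749
-0.78851	-0.63686	-0.66126	-0.12282	-1.18178	1.25669	-0.48702	-0.91808	-1.37905	-1.36292
1.08745	1.07541	1.40914	2.06405	-1.62837	0.18595	-0.68649	-1.09558	0.39613	0.59837
0.4822	-1.18414	-0.55629	-2.26281	-1.86686	-1.02019	-1.49205	1.17591	-0.55444	0.73781
2.23321	0.01754	0.93498	0.21573	1.17962	-0.55759	4.4e-4	-0.55594	-0.93976	2.38984
1.7156	0.78223	0.21621	0.2677	0.37603	-0.578	0.01455	-1.4681	-1.32945	-0.71109
-1.10066	-1.08938	-1.52792	-1.44407	-1.89358	-0.64318	-0.52301	1.13918	1.04299	1.3557
-1.79383	0.62894	0.25873	1.12884	-1.75339	0.15777	0.04525	-0.53318	-0.69983	-1.30125
-2.37823	-1.72622	-1.59591	0.083	-0.32797	-1.401	-1.86307	1.65721	0.37823	-0.25856
-1.47259	-3.41363	-1.30948	-1.14399	0.85807	1.70039	0.67869	-0.52875	-0.74114	-1.85809
0.76469	1.63046	1.13597	1.1182	-0.23114	-1.34444	-0.61884	0.5432	0.73618	1.41319
-1.87793	-1.06861	-0.33175	-0.53407	-0.57131	0.27922	-1.03163	-3.24413	-3.71319	-2.06094
-0.73115	0.73008	0.96075	0.70292	0.13256	-1.20991	-0.6969	-0.28123	-0.78694	-2.81127
-0.02932	0.78696	0.48087	1.63579	-0.62424	-1.25294	-1.61456	-2.67203	-2.60183	-3.67586
1.27146	-0.88262	-0.15695	-1.07363	0.15035	-0.77495	0.07054	0.01696	-0.55339	0.17253
0.30375	-0.00167	0.12848	-1.23097	-1.53599	-1.13028	-0.36964	0.78024	-0.15517	-0.84124
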