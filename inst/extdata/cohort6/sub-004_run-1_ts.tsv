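R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
-0.64046	-1.80285	-2.16648	-0.37062	-0.45562	0.95377	0.96057	0.42847	1.90324	1.88906
0.4783	-0.27849	0.38174	-0.31982	-2.8436	0.04381	-2.02067	-1.56173	-2.18481	-1.23307
0.21927	1.70011	0.23124	-0.12728	1.24735	0.90748	0.41482	2.03759	-0.42577	1.52909
-1.63139	-1.89562	-0.39974	-0.47352	-0.70439	-1.44159	-0.78103	0.95383	-0.24383	0.56311
-0.33413	-0.60883	-0.80602	-0.77008	0.05639	0.79486	-0.09179	-0.02072	-0.80218	-2.64065
0.37205	0.22777	0.27194	0.80863	-0.89633	-1.16283	-1.16067	0.84031	0.53673	0.36191
2.18921	0.95288	2.19755	1.53405	1.18221	0.76065	0.39524	0.14287	1.51696	-0.03522
-0.66645	0.2381	-0.15449	-0.42854	-0.01005	-0.73351	0.985	-0.17781	-0.03092	-0.74369
-0.47558	-0.42303	0.73322	-0.30155	1.66848	1.53643	-0.24655	0.0139	-0.43813	-0.26127
-1.22251	-0.35267	-1.35789	-0.77446	0.89189	0.38094	0.34395	-0.59322	1.06084	0.01988
0.40611	0.66689	2.03154	0.58744	-2.64248	-0.43656	-2.33333	2.27852	1.84953	2.20973
0.88798	0.00976	0.54694	-0.844	1.95	1.55541	2.52012	1.94121	-0.3821	-0.8093
2.21378	2.81289	1.46143	0.80395	1.28161	-0.83067	-1.26516	-1.54092	-0.87125	1.38223
0.56947	2.01103	1.94731	0.7155	0.59915	0.59219	1.37029	0.16767	0.65594	0.24429
-1.89176	-0.47775	-1.6353	-1.33582	-0.19898	-0.00814	-0.42584	-1.16055	-1.25977	-0.12522
1.24734	0.04716	-0.12875	1.41698	0.27772	0.24299	1.31036	0.53217	-0.52976	-0.23496
1.21803	1.70507	1.52466	1.30614	1.06285	0.78817	2.76225	0.56574	1.07	1.17959
0.74189	1.307	1.233	0.62811	1.39764	0.34374	1.18288	0.39581	0.78166	3.14329
-0.31659	-0.12917	-0.60224	-1.36726	0.91173	1.52814	0.22953	-0.26813	-1.42848	-1.25031
0.22436	1.02428	1.02677	0.68206	2.39463	2.81189	0.93073	0.68281	-0.1683	-1.26716
-0.81021	-0.44315	-1.16632	0.77915	-0.24786	-0.28534	0.05962	-0.56761	-0.48368	-1.42575
0.96935	0.13842	1.717	0.03075	-2.00951	0.17978	-0.90077	1.89869	-1.17983	0.33179
-0.18575	-0.91321	-0.65881	-0.17132	-0.33676	-0.96509	-1.8466	-1.79224	-2.02363	-1.51789
-0.57441	-0.80246	-1.3214	-1.68829	-0.43401	-0.32628	-1.10159	-0.0697	-0.18535	-0.09358
-0.08823	1.19638	1.18255	1.59062	-1.73014	-0.05231	-0.68016	2.07323	1.25292	2.21193
-1.62242	-1.48363	-1.78389	-1.66258	-1.07659	-1.21752	-0.49156	-0.31793	-0.43657	-1.06503
0.89142	1.04028	0.6144	0.17296	0.22634	0.33873	0.14086	1.41859	2.61485	-0.20561
0.59405	-0.33665	-0.41369	-0.45757	0.83868	-0.27714	0.01839	-0.41619	-0.62649	0.92417
-1.12882	-6.6e-4	0.28412	0.65606	-0.3134	-1.76429	-2.14038	2.15628	1.96511	1.39146
1.27721	-0.87681	1.40874	0.52485	0.29669	1.22142	0.3454	0.39698	-0.35828	-0.62157
1.16404	-0.11244	-1.00214	0.0235	1.86863	1.56412	0.43123	1.83258	2.46751	2.83202
2.79376	2.58021	2.7667	2.70297	2.20436	1.32865	1.71602	1.38326	1.28088	0.11703
-0.58538	-0.58457	0.03372	-2.21446	-1.15632	-0.25551	-0.56746	-1.70475	-2.03492	-0.37679
-3.96005	-2.99323	-3.46104	-2.54723	-0.87034	0.01409	-1.07879	0.44963	0.04063	-0.81459
-1.34291	-0.71582	-0.41874	0.39295	-0.9499	-1.46068	-0.8255	-1.7691	0.20037	0.80651
-0.0435	0.79018	1.71805	0.77303	1.02385	-2.25396	-0.08277	2.50864	0.24852	1.64576
-3.46462	-1.63203	-1.54475	-1.8699	-1.59101	-1.45063	0.47323	-1.15134	-2.39182	-1.15105
-0.87315	-0.61238	-0.6288	1.24125	0.74515	1.45987	1.17389	-0.12278	-2.65151	-0.39871
-1.08356	-0.81968	0.35438	0.65661	0.11381	0.41303	-1.06344	-2.69251	-1.15723	-2.27806
1.11409	0.91942	0.57672	-0.35821	-2.10622	0.13359	0.98686	1.55729	2.24298	0.52467
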