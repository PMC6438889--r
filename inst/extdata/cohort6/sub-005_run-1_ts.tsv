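R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
0.31274	1.02744	-0.68499	-1.41365	0.22497	0.13126	1.20391	-0.40576	-1.35167	-0.1622
1.27069	0.50854	0.97067	0.91248	0.53758	-0.01242	1.21398	-1.1321	-0.99871	-1.63866
1.47948	2.11565	1.33478	0.48046	0.2828	0.99924	-0.48434	0.22113	-0.65982	0.64804
0.00469	-1.08241	-2.4157	-0.06473	0.62789	-2.08451	0.84577	0.40549	-1.54175	-0.71499
-1.10046	-0.49583	-1.03772	-0.54703	0.13035	-2.67131	-1.12058	-2.67472	-1.89441	-1.92333
-0.63282	1.29256	0.69159	0.6564	-0.3248	1.54967	0.49267	2.20203	0.56354	1.48126
-0.23717	-0.85262	1.0523	-0.96153	0.28978	1.64263	0.99496	-0.25278	-0.76879	0.33573
-0.38808	-0.3111	0.36661	-0.61143	-0.00839	0.21812	0.63402	1.45478	0.87913	0.27681
1.97368	0.72919	1.13469	1.92435	0.13176	0.37199	0.55648	0.90061	0.30252	-1.72859
1.23609	0.13837	2.39028	1.27273	1.10413	0.4135	0.39503	2.76446	1.43233	0.43106
0.99146	1.40091	0.98632	1.32681	-0.02463	-0.26671	0.56813	-2.3927	0.77956	-0.52707
-0.26159	-0.95587	-1.47447	-0.4514	0.82068	0.65526	0.54033	-1.74298	-2.53288	-2.80127
1.34112	0.08694	1.177	1.39927	0.91298	0.54456	-0.26037	-0.43404	-0.95071	2.33514
-0.93706	0.71745	-1.12955	0.20739	-1.73066	-1.88611	-1.98427	0.08631	-0.68333	0.99083
1.93406	1.75356	-0.63491	2.10433	-2.71854	-0.75425	-2.9996	0.0445	1.82243	3.1843
-0.60623	-1.00816	-2.3832	0.11963	1.21666	-0.89276	-1.07193	0.25944	-0.96455	-1.21536
1.15315	-0.60118	-0.46492	-0.49748	1.29603	-0.38915	0.2827	0.15143	-1.46617	-0.43131
-0.46659	-2.40376	0.7925	-0.36788	-1.91486	0.11558	-1.24745	-1.07266	-0.46034	-1.743
-1.51528	-1.15843	-1.0334700000000001	-1.07213	-0.90431	-0.75547	-0.61616	-1.83051	-0.94383	-0.38121
-1.0946	-1.76201	-2.60106	-0.27134	1.00339	1.88092	0.37824	1.54404	0.84659	0.50758
3.46903	2.37162	2.47476	0.40865	-0.2667	1.07373	1.54979	-1.24501	-0.37718	-1.73181
-1.43451	-0.09586	-1.28389	-1.32369	0.6211	0.03604	-0.90848	0.12157	1.35842	-0.05445
0.19388	0.76187	-0.02321	0.00985	-0.55008	-0.79063	-0.52045	-0.4199	-0.36773	0.04587
-0.64465	0.80729	-0.58131	0.23426	-0.80214	-1.60169	1.92099	0.92972	1.10752	0.56448
-0.19744	-2.17252	-1.19065	-2.01431	0.29055	-0.57038	-0.722	-1.24259	-2.00264	-0.04721
0.80484	-0.156	0.96103	0.52809	-1.34347	-2.38161	-0.30644	-1.35743	-0.82879	0.50518
-0.03699	-1.85907	1.34808	-1.48775	0.4641	3.77284	1.65983	0.40784	0.262	1.30435
1.00114	-0.33891	0.47613	0.48679	0.20717	-0.12942	0.90088	-1.12179	-0.93955	-0.49568
0.62811	-0.22622	0.26006	-1.521	0.02405	-0.0195	-0.72314	0.83827	0.93314	-0.3616
-1.45708	-0.158	0.80763	0.03296	-0.47955	-1.50939	-1.65337	-0.44099	0.74864	1.35917
-0.80776	-0.49181	0.71143	-0.70598	1.57796	0.10334	1.2488	0.15375	1.94651	1.97497
0.31476	0.42326	0.5647	-0.20432	0.38395	-0.39105	0.11344	-0.07422	0.26665	-0.92809
0.67767	-0.11491	-0.17835	0.9151	-0.63951	-1.26969	-0.2851	-0.35336	-0.33988	-0.0039
-0.30184	-0.23358	0.3071	0.37675	0.97064	1.14605	1.65263	-1.48405	-2.52543	0.26274
0.37501	-0.29411	-0.81256	-0.23636	-1.21944	-1.45312	0.16179	0.61118	-0.10056	-0.8054
0.18924	-0.79636	-0.63444	-0.68316	1.41498	-0.04376	-0.17808	-1.36579	-1.10342	-0.51253
-0.11087	-0.94213	-1.08949	-1.24971	-1.92402	-0.53984	0.8059	1.10209	-0.32574	-0.13307
1.33265	-0.76498	2.00158	-0.50859	-1.19711	-1.67971	-2.27631	-0.08769	-0.86256	-0.01461
-2.85596	-2.37877	-2.63651	-2.69207	0.1149	-2.01741	-0.25528	-0.54429	-0.85241	-0.52207
0.26805	-0.59447	-2.31052	2.53358	-2.20173	-2.24726	-1.60232	-0.20847	0.42609	0.14373
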