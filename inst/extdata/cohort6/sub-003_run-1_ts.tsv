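R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
0.60766	-0.27109	0.922	-0.52278	1.02793	0.91026	0.58199	1.73002	2.23724	2.23313
-1.62758	-1.27487	-0.88723	-1.19701	0.19428	-1.20851	-1.2616	0.02757	-1.48115	-0.4234
-0.24198	0.43704	0.21945	-0.44068	0.25574	-0.02252	0.91696	1.76449	0.31983	2.25158
0.47751	1.42644	2.67753	1.31241	1.02504	0.06124	1.82597	1.04456	0.06401	0.65571
0.60417	-1.00223	1.51807	0.84814	0.17377	0.06758	-0.13497	0.70586	1.54711	2.61466
1.95797	0.72613	0.48683	1.74087	-0.33915	0.92176	1.80152	2.49541	2.3201	1.81041
-0.07798	-0.58431	-0.76142	-0.77845	-3.53395	-2.66556	-1.1155	-0.33046	1.18456	-0.8631
-0.87974	-2.31097	-0.55049	-1.11439	-1.26134	-1.29135	-0.63272	-2.29219	-0.66577	-1.93875
2.88295	2.44689	1.5785	1.58737	1.16519	2.27458	1.76986	-0.17621	1.3947	0.39014
0.92314	0.1457	1.26556	1.77487	1.19712	0.71819	1.18971	-0.68526	0.13276	-1.02016
-0.97837	-0.86371	-0.65165	-0.07889	1.66598	0.90918	0.0994	1.31917	1.57023	0.31121
-0.82231	0.80289	-1.48573	-0.62833	-2.04294	-2.33033	-1.26553	-1.14754	-0.94541	-1.40756
-1.49743	-0.22931000000000001	-1.58724	-2.95115	2.33301	0.90074	1.2923	-0.09466	0.44863	0.31696
-0.96725	-2.10043	-0.30084	-1.26588	-0.08693	-0.81833	-0.2039	-0.21298	0.26795	2.1699
-1.07745	-0.97066	-0.59645	-0.52427	-1.46296	-1.06006	-0.15834	-0.49397	-1.51468	-1.86557
1.72328	1.69584	-0.07717	0.60347	0.3236	0.41284	-1.2113	-0.50608	-0.46453	-0.39354
-1.30899	0.01821	0.29181	1.36299	-0.79807	-2.14799	-0.49521	-1.00535	0.62042	-1.30598
1.80901	-0.1613	-0.02552	-0.39271	0.58849	-0.81675	1.04142	0.07355	1.4417	0.71266
-2.41427	-1.34252	-1.02322	-1.15284	-0.87853	-1.00755	-1.63252	-0.60047	-1.06448	-1.57721
1.68021	2.251	2.47999	-0.45274	-0.1229	1.27882	-1.05585	1.11492	0.75096	0.84942
0.33972	1.43349	1.22845	0.13653	0.68953	1.48302	-0.94639	1.50283	-1.21163	-2.11702
0.6211	0.89397	0.84697	0.82811	2.85243	1.01007	2.49977	1.32181	0.77999	2.25515
0.07083	0.65686	-1.1793	-0.67116	1.62818	-1.0298	0.55207	-3.04024	-1.26984	-1.70964
-1.92458	-0.12188	0.09017	0.01129	0.688	-0.6995	0.63793	-1.76204	-1.45874	-0.62576
-1.52648	-2.0368	-1.93607	-2.55574	-2.76061	-0.31713	-1.18551	-1.86949	-2.0599	-2.06967
0.58647	-1.77345	0.99241	0.46627	-1.11354	0.06512	1.52829	-1.59761	-2.65747	-2.07904
1.01503	-0.72501	1.37971	0.4963	0.49726	-1.47116	0.1231	-1.09923	-0.78729	-2.20315
-0.46184	-1.35532	-0.42103	-0.17533	-0.38536	0.33843	-1.29862	-1.21156	0.80037	-0.86603
0.50947	1.47324	2.69689	-0.23087	0.13522	0.56401	0.70012	1.76694	2.21073	1.60653
-0.91734	-0.39547	-1.32208	-0.48647	-1.08682	-3.4958	-2.21466	0.32494	0.63667	-0.21967
-1.14941	-0.56141	-2.3445	-0.3422	2.3877	1.25529	0.75903	-1.90379	-2.38306	-0.61247
0.92283	-0.3583	-1.69857	0.43481	-2.23434	0.94464	-0.92321	-0.93816	0.20179	-0.40496
-1.05446	-0.41447	-1.53583	-1.89369	1.19289	0.7507	0.40951	0.38813	0.24437	-0.13067
1.34936	2.31312	2.15911	1.40717	0.86566	1.82933	1.46186	-0.55907	0.75695	1.98358
0.30669	1.31771	1.25186	2.02534	-1.56425	-1.53706	-2.0636	0.29563	0.49182	-0.64942
-0.49046	0.38141	0.29564	0.37188	0.80627	0.26723	0.58957	-2.13413	-0.49967	-0.52635
-1.80273	0.12309	-0.55518	-2.30834	0.86271	0.37434	0.82561	0.52124	0.46431	-3.03638
2.22935	1.03476	2.72822	1.40195	-0.04465	-0.83019	-2.12076	-0.29844	-0.31776	1.47282
2.00032	2.08357	1.51834	2.02563	0.22923	-1.46465	-1.03105	-1.16125	-0.78111	-0.52542
1.53266	0.35245	0.12435	1.16812	1.22439	1.7206	1.19749	0.36985	2.27987	-0.10427
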