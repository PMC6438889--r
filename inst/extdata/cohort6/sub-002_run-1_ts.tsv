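R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
-0.83715	-1.63718	-1.9885	-0.69003	-3.47461	-2.81186	-2.3781	-0.01835	1.58007	-0.55108
0.96336	1.49904	1.03194	2.14557	0.94965	-0.1289	0.13675	2.03193	-0.16277	0.90815
0.46315	2.13434	-0.14564	0.75323	-0.53577	0.88682	0.60111	1.59724	2.04942	0.10768
-0.55524	-0.50245	0.68009	0.7824	0.61814	1.13258	2.39861	1.67873	1.0456	3.1431
-2.11853	-0.84793	-0.68809	-1.5749	0.2856	1.03288	0.62183	1.64075	-0.14056	0.70773
-0.23886	1.77732	0.30694	-0.2991	-1.51932	-2.93656	-2.14791	-1.47376	-1.72748	-1.52396
0.75604	0.47313	0.24042	-1.21739	0.67113	0.44171	-0.47742	-0.80419	-0.89194	0.9977
-0.85291	-0.02058	-0.2897	-0.74598	1.49712	1.0234	1.05212	-1.50016	-0.0641	-1.23929
-1.20463	-0.17125	-0.34415	0.20955	-0.74387	-1.95055	-1.91295	-2.23033	-0.56417	-0.60774
0.24081	-2.08595	-2.04298	-0.70571	-0.01412	0.25044	0.20777	-0.88939	-0.21291	-0.08396
0.30217	1.42067	0.66414	2.16546	0.24384	1.47994	1.15647	-2.04241	-1.11004	-2.18634
-1.2254	-1.4222	-0.36186	-0.33923	2.25986	1.84848	2.80531	0.97117	1.49246	1.65805
-0.78143	-1.42294	0.28077	-1.39529	0.10509	1.34741	-0.02461	1.61941	0.39672	0.53987
-0.8272	-1.40351	-0.40575	0.48428	0.93953	2.18971	1.89403	-0.22074	0.02596	-1.73897
2.47024	0.16733	-1.01094	0.88935	-2.26638	-0.17208	-1.06083	0.76167	-0.21491	0.61199
0.31426	0.54966	1.54902	-0.16172	4.8e-4	0.9289	-0.36882	-0.3059	-0.38337	-1.27223
1.677	-1.15364	1.13419	-1.16099	1.32608	2.40429	1.31281	-0.65627	-0.32382	-0.87005
0.77761	0.96647	0.75154	0.99736	0.32941	0.77308	0.83707	0.59485	0.16996	0.34067
2.72138	2.12063	1.13332	2.85039	1.42596	0.63208	0.8071	-4.34468	-2.0434	-0.27679
1.3832	2.38	1.40176	-0.48831	-0.99279	-1.98537	-2.31364	-1.70713	-2.20908	-0.96409
-0.91847	-1.36372	-0.31697	-0.25913	-1.07859	-1.15639	-1.23444	0.67705	0.41473	0.91292
0.03815	0.84675	-0.6571	0.40127	0.5728	0.01654	0.32736	2.16011	1.34108	0.81241
-0.79601	-0.67713	-1.49071	-2.16203	0.38155	-0.44834	-0.31846	-0.84875	0.86231	-0.83633
0.74383	0.40704	1.59378	0.56516	0.6873	1.09892	0.85796	-0.61052	0.04445	0.0369
1.77821	-0.45503	0.13433	-0.52324	0.93023	1.25545	1.08507	0.64361	1.17694	0.6685
-2.79108	-0.497	1.17927	-0.95952	-0.00986	0.97643	0.06152	1.72146	0.82904	0.90596
-0.21079	-1.05829	-0.87765	-1.02877	0.26966	-1.70103	-1.19199	1.20947	-0.79257	-0.82253
-1.0537	-1.29646	-0.62987	-1.47086	0.98006	1.54039	-0.06702	-0.40676	0.16592	-1.48282
1.59591	0.37158	-1.68133	0.14611	-0.15059	0.27528	-1.20239	0.20586	0.88109	-1.59526
2.17962	1.06043	0.61622	3.19911	1.47504	0.55969	-0.25577	-0.36168	0.5624	0.49284
-0.89399	-0.02638	-1.94859	-1.36373	0.49744	0.44518	0.75455	-0.39688	-0.32943	-0.20798
0.55434	-0.16895	0.53924	0.13886	-0.52951	0.4223	-1.38617	-0.30462	-2.01298	-0.32738
1.17182	0.34864	0.07805	0.35594	1.69331	2.60522	1.08827	-2.92063	-2.04184	-2.22548
1.92695	0.3237	2.58158	1.78079	-0.46691	-0.03924	-1.68022	0.22245	-1.09007	-0.92606
0.80254	0.70931	1.18616	0.11779	0.88364	0.00397	0.59676	0.41002	0.75958	0.48746
-0.65696	-1.18896	0.05768	-1.40229	-0.09179	2.30739	2.46845	0.46782	0.77795	0.93344
-1.71284	-1.16065	-0.8969	-1.0864	-1.13425	-0.29718	-0.03283	1.11866	0.3948	0.05874
2.18202	2.86688	2.22198	2.41049	1.7063	2.75072	0.35785	1.34884	0.44728	-0.22945
2.07867	0.0936	1.3182	0.5202	0.11361	-0.25378	-0.8152	1.10504	1.17041	0.93323
-1.26331	-0.31903	-2.13613	-0.87971	0.64104	1.25346	0.565	-0.68459	-0.99424	-2.52486
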