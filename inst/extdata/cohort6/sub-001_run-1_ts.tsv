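R001	R002	R003	R004	R005	R006	R007	R008	R009	R010
1.32536	0.13918	1.24625	-0.67921	-0.01703	0.45618	-0.97586	1.2149	0.9928	1.79339
0.18852	0.31287	0.01776	-0.78646	1.19993	-0.19488	-1.22899	-2.11055	0.36409	-1.71166
0.49285	-0.26399	-0.75003	-0.7633	2.5208	1.76466	0.62958	1.73346	0.19232	1.51295
-0.50529	-0.22786	-0.13114	-0.64969	-1.54435	-1.14068	-1.63271	-0.71315	1.04711	2.71513
1.20458	-0.96254	-0.42966	0.81868	-3.43171	-3.21201	-2.62236	-0.02757	0.02276	-0.27867
0.8053	0.70679	0.57789	-0.26297	-1.68536	0.75073	-0.1353	-0.85127	-0.16212	-0.62291
-0.59266	-1.23482	1.17623	-1.79275	-3.02298	-1.36004	0.53429	-0.78775	0.22618	0.55699
0.24281	0.1665	-1.34581	-0.95458	-1.51594	-1.99087	-0.71855	-0.30417	-0.58757	-0.5239
-0.47027	0.48774	0.32526	0.67999	0.8563	0.01379	0.54877	0.41499	-0.32017	0.50385
1.59995	1.80976	0.06573	1.26054	1.58853	1.83934	0.47424	-0.67723	1.04466	0.08491
1.07845	0.47633	0.87623	-0.0326	1.16221	0.36957	0.77911	0.22419	0.67119	0.99843
0.24539	0.23929	0.82871	1.21928	1.8283	0.0445	1.00005	0.96479	0.6602	2.18083
1.12319	0.66798	0.01232	-0.5378	0.5986	2.4004	0.24716	0.26389	2.7146	0.81456
-2.81827	-1.24709	-2.36452	-2.20008	1.59931	-0.54428	1.86482	-1.98884	-0.74293	-1.4247
1.79057	0.32541	0.30866	-0.08111	2.69549	1.95523	2.7391200000000002	1.17554	0.75185	0.01903
-0.03927	-0.2305	1.01761	0.49482	-0.76471	0.80919	-0.34127999999999997	-0.41263	0.35157	0.31435
2.54689	0.63413	0.22755	1.12433	0.08045	1.12458	0.57516	0.71734	2.09215	0.14572
1.44013	0.91559	0.70611	0.67896	-0.35955	-1.22148	0.8662	0.5135	-0.64173	-1.35384
0.59307	-0.57342	0.74616	1.24508	-0.55932	-0.83955	0.84916	0.13673	0.46509	0.79926
-1.94132	-2.67112	-1.53721	-1.43956	-1.425	-1.38166	-1.04952	-0.72957	-0.44333	-0.17481
0.26405	0.61685	0.74465	0.443	-0.42341	0.35294	0.26042	0.86931	-0.33079	0.50884
0.1098	0.2646	0.02015	0.2128	0.25782	-0.35032	-2.55191	-2.29785	-0.03174	-0.0567
0.62209	1.28342	2.74153	0.23173	0.20328	0.84793	1.04044	-1.67019	-0.38372	-0.62833
0.6715	-0.39971	1.65959	0.51859	-0.54551	0.18841	-0.75581	1.89266	-1.008	0.32502
-0.90365	-0.38635	1.54504	0.29806	0.9339	-0.82364	1.66883	1.24371	-0.81293	0.48922
1.37013	0.60275	-0.59939	0.77345	-0.68315	-2.23448	-1.43196	0.91215	0.86149	1.17035
-0.97059	-2.0554	-1.42315	-2.29111	1.08779	-0.14586	-0.39846	-0.56135	-1.78742	-1.81908
-1.15666	-0.58966	-0.89301	-0.79309	-1.02093	0.48901	0.4182	2.10352	1.16333	1.43212
-0.44801	0.59323	-0.40854	-2.13275	0.20749	1.31417	0.70236	-1.08638	-0.33344	0.68917
0.22848	0.48052	-0.03269	-1.30915	-0.04103	-0.11282	1.71862	-1.87809	-0.57747	-2.28027
1.20721	2.01073	1.29946	1.03332	0.36305	-0.57013	1.86173	-1.35723	-0.14746	-0.40382
0.18436	0.15005	-0.82897	1.32775	1.11942	0.75971	0.40841	1.03384	0.75273	1.26558
-1.40902	-0.86419	-2.91286	0.51335	-0.62733	1.15211	-0.62339	0.44862	-0.17122	-0.17257
1.43698	0.51577	-0.97193	1.46485	-2.26313	-1.40649	-0.78402	-0.20924	0.05815	-0.94235
-1.37878	-1.11994	1.25821	0.13372	1.01764	0.78192	0.83509	1.30065	1.53764	-0.14715
-1.75217	-1.02428	-0.85647	-1.49885	-3.57347	-1.5837	-1.16039	0.81879	-0.28902	0.80697
-0.78025	1.26969	-0.06818	-0.00223	-0.74037	-0.24753	-2.0226	-1.51415	-0.57546	-0.55837
-1.3022	-0.99527	-1.85579	-0.84409	-0.15501	-0.61089	-0.99084	-0.79078	-0.93362	-1.57443
1.44805	0.85048	1.01309	-0.41897	-0.11199	0.62521	-0.64787	-0.79463	0.25978	1.40857
0.63475	0.05448	0.42468	0.68808	-0.82132	-1.42625	-3.12432	0.35993000000000003	1.24485	0.39686
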