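rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs000001	A	T	0.3182	-0.00257166	0.00752106	0.7324	184305
rs000002	T	C	0.6331	0.00478075	0.00726855	0.5107	184305
rs000003	C	T	0.4908	0.0022823	0.00700747	0.7447	184305
rs000004	G	C	0.6765	0.00753145	0.00748836	0.3145	184305
rs000005	C	T	0.2128	-0.0124874	0.00855912	0.1446	184305
rs000006	T	C	0.61	0.00735909	0.00718225	0.3055	184305
rs000007	G	T	0.4004	0.00158229	0.00714957	0.8248	184305
rs000008	T	A	0.7945	-0.0192016	0.00866972	0.02677	184305
rs000009	A	C	0.1333	-0.00242509	0.0103064	0.814	184305
rs000011	G	A	0.6565	0.0038665	0.00737695	0.6002	184305
rs000012	A	G	0.3348	0.0122966	0.00742316	0.09762	184305
rs000013	G	A	0.9071	0.00477672	0.0120676	0.6922	184305
rs000014	G	T	0.3386	-0.00959679	0.00740256	0.1948	184305
rs000015	G	A	0.8992	-0.0111337	0.0116359	0.3386	184305
rs000016	C	T	0.2735	-0.00804118	0.00785889	0.3062	184305
rs000017	G	A	0.5802	0.00547996	0.00709819	0.4401	184305
rs000018	C	G	0.2996	-0.013973	0.0076474	0.06768	184305
rs000019	G	A	0.6759	0.00670201	0.00748474	0.3706	184305
rs000020	A	G	0.3635	0.00193251	0.00728293	0.7907	184305
rs000021	G	A	0.5823	0.00233488	0.00710317	0.7424	184305
rs000022	A	C	0.2507	-0.00296809	0.00808263	0.7135	184305
rs000023	G	C	0.6063	0.00385172	0.0071702	0.5911	184305
rs000024	C	T	0.1814	-0.00692737	0.00909082	0.446	184305
rs000025	T	C	0.5008	-0.0132617	0.00700629	0.05838	184305
rs000026	A	G	0.166	0.0241721	0.00941501	0.01025	184305
rs000027	T	G	0.5248	0.0034253	0.00701492	0.6253	184305
rs000028	G	T	0.4491	-0.00839411	0.00704287	0.2333	184305
rs000029	C	A	0.5507	-0.00815674	0.00704258	0.2468	184305
rs000030	A	T	0.1729	0.000579764	0.00926363	0.9501	184305
rs000031	C	A	0.8132	0.00131759	0.00898816	0.8835	184305
rs000032	A	C	0.4754	0.00443292	0.00701478	0.5274	184305
rs000033	T	C	0.7092	-9.38763e-05	0.00771394	0.9903	184305
rs000034	C	T	0.4944	-0.00150648	0.00700672	0.8298	184305
rs000035	T	C	0.6282	-6.08097e-05	0.0072486	0.9933	184305
rs000036	A	C	0.4907	-0.00662992	0.0070075	0.3441	184305
rs000037	T	G	0.9171	-0.0157391	0.0127049	0.2154	184305
rs000038	A	T	0.4162	0.000737968	0.00710681	0.9173	184305
rs000039	T	A	0.8083	-0.00450836	0.00889939	0.6124	184305
rs000040	C	G	0.3016	-0.00478955	0.00763291	0.5303	184305
rs000041	G	C	0.9077	-0.00416855	0.0121028	0.7305	184305
rs000042	A	G	0.2682	0.000616406	0.00790737	0.9379	184305
rs000043	T	C	0.8261	0.010655	0.00924255	0.249	184305
rs000044	C	G	0.1544	-8.91112e-05	0.00969508	0.9927	184305
rs000045	T	C	0.5576	0.00154543	0.00705324	0.8266	184305
rs000046	C	G	0.491	0.00307143	0.00700742	0.6612	184305
rs000047	G	C	0.5915	-0.00218765	0.00712663	0.7589	184305
rs000048	G	T	0.2121	-0.010569	0.00856943	0.2174	184305
rs000049	T	C	0.5503	0.000657281	0.00704201	0.9256	184305
rs000050	A	G	0.2942	0.0164905	0.00768768	0.03195	184305
rs000051	G	C	0.8661	-0.0170576	0.0102869	0.09728	184305
rs000052	A	T	0.4307	-0.000528245	0.00707456	0.9405	184305
rs000053	T	G	0.6616	-0.0100594	0.00740363	0.1742	184305
rs000054	C	G	0.3915	-0.00710189	0.00717731	0.3224	184305
rs000055	G	C	0.8107	0.00299761	0.00894236	0.7375	184305
rs000056	A	T	0.4598	-0.0143033	0.00702904	0.04186	184305
rs000057	G	C	0.6288	-0.00106432	0.00725099	0.8833	184305
rs000058	G	T	0.4489	-0.00868865	0.00704316	0.2173	184305
rs000059	G	A	0.5323	-0.00687451	0.00702095	0.3275	184305
rs000060	C	T	0.3617	0.00327543	0.00729073	0.6532	184305
rs000061	T	C	0.8954	-0.0134327	0.0114468	0.2406	184305
rs000062	C	T	0.2733	-0.00354309	0.00786068	0.6522	184305
rs000063	T	G	0.8183	0.00700656	0.00908498	0.4406	184305
rs000064	A	G	0.3884	-0.000682346	0.00718761	0.9244	184305
rs000065	G	A	0.8521	0.00528989	0.00986798	0.5919	184305
rs11749751	C	T	0.1304	0.00667341	0.010403	0.5212	184305
rs2335349	C	A	0.8437	0.00993842	0.00964682	0.3029	184305
rs3740390	G	T	0.2882	-0.00634734	0.00773449	0.4118	184305
rs61942416	G	A	0.8151	0.0139899	0.00902368	0.1211	184305
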