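rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs000001	A	T	0.3182	-0.0218972	0.0035318	5.646e-10	184765
rs000002	C	T	0.3669	-0.0197967	0.00341323	6.631e-09	184765
rs000003	C	T	0.4908	-0.0213891	0.00329063	8.032e-11	184765
rs000004	C	G	0.3235	0.0196921	0.00351645	2.144e-08	184765
rs000005	C	T	0.2128	0.0285368	0.00401927	1.248e-12	184765
rs000006	C	T	0.39	0.0151772	0.0033727	6.795e-06	184765
rs000007	G	T	0.4004	-0.0151081	0.00335736	6.795e-06	184765
rs000008	A	T	0.2055	0.0183204	0.0040712	6.795e-06	184765
rs000009	A	C	0.1333	-0.021779	0.00483978	6.795e-06	184765
rs80144387	C	G	0.2889	-0.0163323	0.00362941	6.795e-06	184765
rs000011	A	G	0.3435	-0.0155886	0.00346413	6.795e-06	184765
rs000012	A	G	0.3348	0.0156862	0.00348583	6.795e-06	184765
rs000013	A	G	0.0929	-0.0255007	0.00566682	6.795e-06	184765
rs000014	G	T	0.3386	0.0156427	0.00347616	6.795e-06	184765
rs000015	A	G	0.1008	0.0245883	0.00546408	6.795e-06	184765
rs000016	C	T	0.2735	-0.016607	0.00369044	6.795e-06	184765
rs000017	A	G	0.4198	0.0149995	0.00333323	6.795e-06	184765
rs000018	C	G	0.2996	0.0161601	0.00359113	6.795e-06	184765
rs000019	A	G	0.3241	0.0158164	0.00351475	6.795e-06	184765
rs000020	A	G	0.3635	-0.0153899	0.00341998	6.795e-06	184765
rs000021	A	G	0.4177	0.01501	0.00333557	6.795e-06	184765
rs000022	A	C	0.2507	-0.0170798	0.00379551	6.795e-06	184765
rs000023	C	G	0.3937	-0.0151517	0.00336704	6.795e-06	184765
rs000024	C	T	0.1814	0.0192103	0.00426895	6.795e-06	184765
rs000025	C	T	0.4992	-0.0148053	0.00329007	6.795e-06	184765
rs000026	A	G	0.166	-0.0198953	0.00442118	6.795e-06	184765
rs000027	G	T	0.4752	0.0148236	0.00329412	6.795e-06	184765
rs000028	G	T	0.4491	0.0148826	0.00330725	6.795e-06	184765
rs000029	A	C	0.4493	-0.014882	0.00330712	6.795e-06	184765
rs000030	A	T	0.1729	0.0195754	0.00435009	6.795e-06	184765
rs000031	A	C	0.1868	0.0189933	0.00422073	6.795e-06	184765
rs000032	A	C	0.4754	0.0148233	0.00329406	6.795e-06	184765
rs000033	C	T	0.2908	0.0163007	0.00362238	6.795e-06	184765
rs000034	C	T	0.4944	0.0148062	0.00329028	6.795e-06	184765
rs000035	C	T	0.3718	-0.0153174	0.00340386	6.795e-06	184765
rs000036	A	C	0.4907	0.0148079	0.00329064	6.795e-06	184765
rs000037	G	T	0.0829	0.0268474	0.00596609	6.795e-06	184765
rs000038	A	T	0.4162	0.0150177	0.00333728	6.795e-06	184765
rs000039	A	T	0.1917	-0.0188057	0.00417905	6.795e-06	184765
rs000040	C	G	0.3016	0.0161295	0.00358432	6.795e-06	184765
rs000041	C	G	0.0923	0.025575	0.00568333	6.795e-06	184765
rs000042	A	G	0.2682	0.0167094	0.00371321	6.795e-06	184765
rs000043	C	T	0.1739	-0.0195309	0.00434019	6.795e-06	184765
rs000044	C	G	0.1544	-0.0204871	0.0045527	6.795e-06	184765
rs000045	C	T	0.4424	-0.0149045	0.00331212	6.795e-06	184765
rs000046	C	G	0.491	-0.0148077	0.0032906	6.795e-06	184765
rs000047	C	G	0.4085	-0.0150596	0.00334658	6.795e-06	184765
rs000048	G	T	0.2121	0.0181085	0.0040241	6.795e-06	184765
rs000049	C	T	0.4497	0.0148808	0.00330685	6.795e-06	184765
rs000050	A	G	0.2942	0.0162452	0.00361005	6.795e-06	184765
rs000051	C	G	0.1339	0.0217377	0.0048306	6.795e-06	184765
rs000052	A	T	0.4307	0.0149496	0.00332213	6.795e-06	184765
rs000053	G	T	0.3384	-0.015645	0.00347666	6.795e-06	184765
rs000054	C	G	0.3915	0.0151667	0.00337038	6.795e-06	184765
rs000055	C	G	0.1893	-0.0188965	0.00419923	6.795e-06	184765
rs000056	A	T	0.4598	0.0148534	0.00330076	6.795e-06	184765
rs000057	C	G	0.3712	0.0153224	0.00340498	6.795e-06	184765
rs000058	G	T	0.4489	-0.0148832	0.00330739	6.795e-06	184765
rs000059	A	G	0.4677	-0.0148363	0.00329696	6.795e-06	184765
rs000060	C	T	0.3617	-0.0154064	0.00342364	6.795e-06	184765
rs000061	C	T	0.1046	-0.0241887	0.00537528	6.795e-06	184765
rs000062	C	T	0.2733	0.0166108	0.00369129	6.795e-06	184765
rs000063	G	T	0.1817	0.0191979	0.0042662	6.795e-06	184765
rs000064	A	G	0.3884	-0.0151885	0.00337522	6.795e-06	184765
rs000065	A	G	0.1479	0.0157552	0.00463389	0.0006739	184765
rs11749751	C	T	0.1304	-0.0214946	0.00488514	1.083e-05	184765
rs2335349	A	C	0.1563	-0.0199322	0.00453004	1.083e-05	184765
rs3740390	G	T	0.2882	0.0159809	0.00363203	1.083e-05	184765
rs61942416	A	G	0.1849	-0.0186446	0.00423742	1.083e-05	184765
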