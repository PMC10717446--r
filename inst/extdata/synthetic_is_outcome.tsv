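rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs000001	A	T	0.3182	0.0051917	0.00854577	0.5435	440328
rs000002	T	C	0.6331	-0.00351373	0.00825885	0.6705	440328
rs000003	C	T	0.4908	0.00959627	0.0079622	0.2281	440328
rs000004	G	C	0.6765	-0.00705502	0.00850861	0.407	440328
rs000005	C	T	0.2128	-0.00289442	0.00972527	0.766	440328
rs000006	T	C	0.61	-0.000250627	0.0081608	0.9755	440328
rs000007	G	T	0.4004	-0.00281424	0.00812366	0.729	440328
rs000008	T	A	0.7945	0.0113714	0.00985092	0.2484	440328
rs000009	A	C	0.1333	0.00144654	0.0117106	0.9017	440328
rs80144387	G	C	0.7111	0.00122988	0.00878194	0.8886	440328
rs000011	A	G	0.3435	-0.00799708	0.00838203	0.34	440328
rs000012	G	A	0.6652	-0.00643504	0.00843453	0.4455	440328
rs000013	A	G	0.0929	-0.000166915	0.0137118	0.9903	440328
rs000014	T	G	0.6614	0.000907656	0.00841113	0.9141	440328
rs000015	A	G	0.1008	0.0021156	0.0132212	0.8729	440328
rs000016	T	C	0.7265	-0.00278069	0.00892963	0.7555	440328
rs000017	A	G	0.4198	0.00324727	0.00806529	0.6872	440328
rs000018	G	C	0.7004	0.00757753	0.00868932	0.3832	440328
rs000019	A	G	0.3241	-0.00457606	0.00850451	0.5905	440328
rs000020	G	A	0.6365	-0.00384433	0.0082752	0.6422	440328
rs000021	A	G	0.4177	0.0108926	0.00807094	0.1771	440328
rs000022	C	A	0.7493	-0.00482871	0.00918385	0.599	440328
rs000023	C	G	0.3937	-0.000732869	0.00814711	0.9283	440328
rs000024	T	C	0.8186	-0.00447938	0.0103294	0.6645	440328
rs000025	C	T	0.4992	0.0111788	0.00796087	0.1603	440328
rs000026	G	A	0.834	-0.00201628	0.0106978	0.8505	440328
rs000027	G	T	0.4752	-0.00117664	0.00797067	0.8826	440328
rs000028	T	G	0.5509	0.00173019	0.00800243	0.8288	440328
rs000029	A	C	0.4493	0.000778732	0.0080021	0.9225	440328
rs000030	T	A	0.8271	0.0137359	0.0105258	0.1919	440328
rs000031	A	C	0.1868	0.0059418	0.0102127	0.5607	440328
rs000032	C	A	0.5246	-0.0111466	0.00797051	0.162	440328
rs000033	C	T	0.2908	0.00252032	0.00876493	0.7737	440328
rs000034	T	C	0.5056	0.0047063	0.00796136	0.5544	440328
rs000035	C	T	0.3718	0.00722112	0.00823619	0.3806	440328
rs000036	C	A	0.5093	-0.00767785	0.00796223	0.3349	440328
rs000037	G	T	0.0829	-0.0325113	0.0144359	0.02432	440328
rs000038	T	A	0.5838	0.00607132	0.00807508	0.4521	440328
rs000039	A	T	0.1917	0.0102152	0.0101119	0.3124	440328
rs000040	G	C	0.6984	-0.0135838	0.00867285	0.1173	440328
rs000041	C	G	0.0923	-0.00805895	0.0137517	0.5579	440328
rs000042	G	A	0.7318	0.00151917	0.00898471	0.8657	440328
rs000043	C	T	0.1739	-0.000388024	0.0105018	0.9705	440328
rs000044	G	C	0.8456	-0.0160521	0.011016	0.1451	440328
rs000045	C	T	0.4424	0.00372128	0.00801421	0.6424	440328
rs000046	G	C	0.509	0.00143576	0.00796215	0.8569	440328
rs000047	C	G	0.4085	-0.00245555	0.0080976	0.7617	440328
rs000048	T	G	0.7879	0.018361	0.00973697	0.05934	440328
rs000049	C	T	0.4497	-0.00257095	0.00800145	0.748	440328
rs000050	G	A	0.7058	0.0022913	0.0087351	0.7931	440328
rs000051	C	G	0.1339	0.00612032	0.0116884	0.6005	440328
rs000052	T	A	0.5693	-0.00852449	0.00803844	0.2889	440328
rs000053	G	T	0.3384	0.0139845	0.00841234	0.09644	440328
rs000054	G	C	0.6085	0.00260665	0.00815518	0.7492	440328
rs000055	C	G	0.1893	0.00460947	0.0101607	0.6501	440328
rs000056	T	A	0.5402	-0.00917097	0.00798671	0.2509	440328
rs000057	C	G	0.3712	-0.0137941	0.00823891	0.09408	440328
rs000058	T	G	0.5511	-0.00170201	0.00800276	0.8316	440328
rs000059	A	G	0.4677	-0.00175682	0.00797752	0.8257	440328
rs000060	T	C	0.6383	-0.00305778	0.00828406	0.712	440328
rs000061	C	T	0.1046	-0.0151398	0.0130063	0.2444	440328
rs000062	T	C	0.7267	0.000661636	0.00893166	0.9409	440328
rs000063	G	T	0.1817	-0.00843093	0.0103228	0.4141	440328
rs000064	G	A	0.6116	0.00408013	0.00816689	0.6174	440328
rs000065	A	G	0.1479	0.0206215	0.0112124	0.06589	440328
rs11749751	T	C	0.8696	-0.000294217	0.0118204	0.9801	440328
rs2335349	A	C	0.1563	-0.00506252	0.0109612	0.6442	440328
rs3740390	T	G	0.7118	-0.00224477	0.00878828	0.7984	440328
rs61942416	A	G	0.1849	-0.01746	0.0102531	0.08859	440328
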