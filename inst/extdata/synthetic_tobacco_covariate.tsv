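rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs000001	A	T	0.3182	-0.0124598	0.00136768	8.225e-20	1232091
rs000002	C	T	0.3669	-0.00902368	0.00132176	8.67e-12	1232091
rs000003	C	T	0.4908	-0.00625475	0.00127429	9.181e-07	1232091
rs000004	C	G	0.3235	0.00471274	0.00136173	0.0005385	1232091
rs000005	C	T	0.2128	0.0138832	0.00155645	4.672e-19	1232091
rs000006	C	T	0.39	0.0115745	0.00130607	7.853e-19	1232091
rs000007	G	T	0.4004	0.00189218	0.00130013	0.1456	1232091
rs000008	A	T	0.2055	0.00724686	0.00157656	4.294e-06	1232091
rs000009	A	C	0.1333	-0.00178295	0.00187419	0.3414	1232091
rs80144387	C	G	0.2889	-0.00742281	0.00140548	1.282e-07	1232091
rs000011	A	G	0.3435	-0.00837359	0.00134148	4.319e-10	1232091
rs000012	A	G	0.3348	0.00514785	0.00134988	0.000137	1232091
rs000013	A	G	0.0929	-0.0051864	0.00219446	0.01811	1232091
rs000014	G	T	0.3386	0.00646183	0.00134613	1.584e-06	1232091
rs000015	A	G	0.1008	0.0220452	0.00211595	2.04e-25	1232091
rs000016	C	T	0.2735	-0.00657775	0.00142911	4.171e-06	1232091
rs000017	A	G	0.4198	0.0123009	0.00129078	1.576e-21	1232091
rs000018	C	G	0.2996	0.0114995	0.00139066	1.35e-16	1232091
rs000019	A	G	0.3241	0.00447847	0.00136108	0.001001	1232091
rs000020	A	G	0.3635	-0.00777731	0.00132438	4.295e-09	1232091
rs000021	A	G	0.4177	0.0142014	0.00129169	4.065e-28	1232091
rs000023	C	G	0.3937	-0.00434741	0.00130388	0.0008554	1232091
rs000024	C	T	0.1814	0.0132496	0.00165314	1.103e-15	1232091
rs000026	A	G	0.166	-0.0193107	0.00171209	1.666e-29	1232091
rs000027	G	T	0.4752	0.00567612	0.00127564	8.602e-06	1232091
rs000029	A	C	0.4493	-0.011101	0.00128067	4.393e-18	1232091
rs000030	A	T	0.1729	0.0124669	0.00168456	1.355e-13	1232091
rs000032	A	C	0.4754	0.0011542	0.00127562	0.3656	1232091
rs000033	C	T	0.2908	0.000662009	0.00140276	0.637	1232091
rs000034	C	T	0.4944	0.00345031	0.00127415	0.00677	1232091
rs000035	C	T	0.3718	-0.00731418	0.00131814	2.875e-08	1232091
rs000037	G	T	0.0829	0.0240464	0.00231035	2.277e-25	1232091
rs000038	A	T	0.4162	0.00614592	0.00129235	1.978e-06	1232091
rs000039	A	T	0.1917	-0.00745054	0.00161833	4.148e-06	1232091
rs000040	C	G	0.3016	0.00845861	0.00138802	1.101e-09	1232091
rs000042	A	G	0.2682	0.00816162	0.00143793	1.379e-08	1232091
rs000043	C	T	0.1739	-0.00683635	0.00168073	4.752e-05	1232091
rs000044	C	G	0.1544	-0.0119591	0.00176302	1.175e-11	1232091
rs000045	C	T	0.4424	0.001191	0.00128261	0.3531	1232091
rs000046	C	G	0.491	-0.00763523	0.00127428	2.075e-09	1232091
rs000047	C	G	0.4085	-0.00292656	0.00129596	0.02393	1232091
rs000048	G	T	0.2121	0.00708742	0.00155832	5.413e-06	1232091
rs000049	C	T	0.4497	0.00553232	0.00128057	1.559e-05	1232091
rs000050	A	G	0.2942	0.0111855	0.00139798	1.232e-15	1232091
rs000053	G	T	0.3384	-0.00636067	0.00134633	2.307e-06	1232091
rs000054	C	G	0.3915	0.00648325	0.00130517	6.787e-07	1232091
rs000055	C	G	0.1893	-0.00231257	0.00162614	0.155	1232091
rs000056	A	T	0.4598	0.00670417	0.00127821	1.563e-07	1232091
rs000057	C	G	0.3712	0.00892994	0.00131857	1.266e-11	1232091
rs000058	G	T	0.4489	-0.0062944	0.00128078	8.901e-07	1232091
rs000059	A	G	0.4677	-0.00757598	0.00127674	2.959e-09	1232091
rs000060	C	T	0.3617	-0.0044865	0.0013258	0.0007144	1232091
rs000061	C	T	0.1046	-0.00321804	0.00208156	0.1221	1232091
rs000062	C	T	0.2733	0.00175685	0.00142944	0.2191	1232091
rs000063	G	T	0.1817	0.0061689	0.00165208	0.0001884	1232091
rs000064	A	G	0.3884	-0.0119024	0.00130704	8.518e-20	1232091
rs000065	A	G	0.1479	0.0113853	0.00179446	2.229e-10	1232091
rs11749751	C	T	0.1304	-0.00367316	0.00189176	0.05218	1232091
rs2335349	A	C	0.1563	-0.00656734	0.00175424	0.0001813	1232091
rs3740390	G	T	0.2882	0.00664115	0.00140649	2.338e-06	1232091
rs61942416	A	G	0.1849	-0.00113657	0.00164093	0.4885	1232091
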