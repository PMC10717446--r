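label	outcome_group	estimate	ci_low	ci_high	design
synthetic_study_01	CAD	2.2328	1.1594	4.2999	retrospective
synthetic_study_02	CAD	0.95722	0.48945	1.872	retrospective
synthetic_study_03	CAD	1.7748	1.3816	2.2801	retrospective
synthetic_study_04	CAD	1.6472	1.0131	2.6784	retrospective
synthetic_study_05	CAD	1.2732	1.0211	1.5876	retrospective
synthetic_study_06	CAD	1.8678	1.1605	3.0063	retrospective
synthetic_study_07	IS	2.2034	1.6255	2.9867	prospective
synthetic_study_08	IS	1.1344	0.76088	1.6912	prospective
synthetic_study_09	IS	1.3321	1.0788	1.6449	prospective
synthetic_study_10	IS	1.5069	0.96369	2.3563	prospective
synthetic_study_11	IS	1.3573	1.0258	1.796	prospective
synthetic_study_12	IS	1.2876	0.8907	1.8613	prospective
synthetic_study_13	ASCVD	1.1926	1.0815	1.3151	prospective
synthetic_study_14	ASCVD	1.2269	1.1151	1.35	prospective
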