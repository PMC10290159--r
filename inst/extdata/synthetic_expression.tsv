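gene	0	3	6	9	12	15	18	21	24	27	30	33	36	39	42	45
ARNTL	66.075	53.595	31.622	43.088	50.721	69.816	99.577	85.227	62.078	56.512	34.691	38.816	47.904	64.49	100.917	81.453
CLOCK	50.191	49.518	39.6	40.452	36.852	46.999	50.264	58.859	55.031	44.682	39.401	41.628	40.308	41.012	43.685	52.51
PER1	20.914	31.803	35.434	41.668	40.5	30.269	18.697	18.733	20.312	33.11	42.716	37.114	43.512	28.445	21.063	17.68
PER2	27.98	47.054	56.08	65.685	57.794	53.5	43.275	27.701	30.557	39.337	60.928	63.013	66.692	70.467	35.717	26.078
PER3	5.692	6.134	8.726	11.75	9.108	9.393	7.937	5.693	5.03	6.464	8.063	9.352	11.293	10.654	7.167	5.175
CRY1	23.977	25.523	32.743	36.787	32.482	44.975	33.297	23.354	26.044	32.123	36.092	36.683	51.335	40.245	34.962	27.475
CRY2	24.059	24.982	25.006	28.697	34.421	29.159	38.553	21.315	20.889	18.779	26.935	28.061	32.744	38.073	29.4	29.285
NR1D1	47.254	52.082	59.679	60.977	38.375	24.37	17.556	19.914	38.67	50.37	64.255	53.37	35.081	24.832	16.924	22.605
NR1D2	28.859	43.801	44.748	55.087	27.87	23.95	16.079	19.668	24.663	36.401	41.111	47.3	38.076	20.8	16.287	21.696
ROR	22.579	19.846	23.694	25.583	32.03	33.118	30.517	30.988	32.909	20.016	23.851	30.192	36.763	39.368	46.605	37.684
DBP	16.796	23.066	34.457	27.282	23.332	18.38	12.773	8.258	14.444	19.994	24.792	27.82	23.993	14.651	11.43	10.236
NFIL3	15.917	12.217	10.525	12.148	17.906	16.151	22.987	15.247	12.419	10.674	9.249	10.349	16.732	18.843	18.601	18.82
PPARA	21.394	15.893	21.326	18.815	19.284	22.998	23.448	19.185	17.358	14.175	12.697	17.393	21.911	17.513	21.032	16.853
CES2	52.156	55.788	68.72	71.64	67.221	55.745	50.326	56.346	62.893	86.907	101.48	76.736	73.882	74.297	59.174	69.283
ABCB	16.943	13.452	17.932	20.001	24.06	20.089	17.904	19.903	19.343	14.828	14.061	21.372	21.728	17.873	17.873	16.032
ABCC	38.322	39.368	45.503	54.141	55.984	52.767	43.641	37.11	38.921	42.707	53.041	54.558	56.771	46.916	51.695	42.29
UGT1A1	0.046	0.035	0.059	0.065	0.05	0.047	0.05	0.044	0.049	0.049	0.052	0.068	0.066	0.046	0.053	0.042
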