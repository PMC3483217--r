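network	gene	common_name	pct_delta_mean	pct_delta_max
WLN	T23D8.3	T23D8.3	25.7	34.7
WLN	F37C12.9	rps-14	16.6	21.7
WLN	T09A5.10	lin-5	16.4	8.7
WLN	C03C10.3	rnr-2	14.2	21.7
WLN	F54E7.2	rps-12	11.6	21.7
WLN	F09F7.3	F09F7.3	8.1	21.7
WLN	C38D4.3	mel-28	6.5	8.7
WLN	T20B12.8	hmg-4	6.5	0.0
WLN	F35G12.10	asb-1	6.4	0.0
WLN	F26F4.11	rpb-8	6.4	0.0
WLN	C47D12.2	C47D12.2	5.5	8.7
WLN	K10B3.7	gpd-3	5.3	0.0
WLN	R144.2	R144.2	-18.9	-25.0
WLN	K07D4.3	rpn-11	-19.3	-25.0
WLN	B0285.1	B0285.1	-22.2	-25.0
WLN	R13G10.1	dpy-27	-23.5	-25.0
WLN	W07B3.2	gei-4	-27.0	-38.0
HLN	C03C10.3	rnr-2	14.2	21.7
HLN	R02D3.3	R02D3.3	13.0	21.7
HLN	F10B5.6	emb-27	10.5	8.7
HLN	F29G9.3	aps-1	7.9	0.0
HLN	T09B4.10	chn-1	7.1	8.7
HLN	F26F4.11	rpb-8	6.4	0.0
HLN	F28D9.1	rsr-1	6.1	0.0
HLN	F18A1.5	rpa-1	5.1	21.7
HLN	C01H6.5	nhr-23	4.9	8.7
HLN	Y40B1A.4	sptf-3	-22.9	-37.0
HLN	ZK1058.2	pat-3	-28.1	-50.0
HLN	C52E4.4	rpt-1	-28.4	-50.0
HLN	F26H9.6	rab-5	-38.0	-50.0
HLN	D1014.3	snap-1	-39.9	-50.0
HLN	K02D10.5	K02D10.5	-48.6	-72.0
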