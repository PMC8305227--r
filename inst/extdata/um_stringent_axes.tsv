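mi_id	r_mi_m	m_id	TarBase	miRTarBase	lnc_id	r_mi_lnc	miRcode	LncBase_V	LncBase_P	Encori	r_lnc_m
hsa-miR-199a-5p	-0.65	CDCA7L	1	0	LINC00518	-0.66	1	0	0	0	0.65
hsa-miR-199a-5p	-0.65	CDCA7L	1	0	SNHG7	-0.69	1	0	0	0	0.73
hsa-miR-195-5p	-0.60	SDC3	1	0	LINC01128	-0.67	0	0	0	1	0.72
hsa-miR-199a-5p	-0.66	RPL15	1	0	LINC00518	-0.66	1	0	0	0	0.64
hsa-miR-199a-5p	-0.66	RPL15	1	0	SNHG7	-0.69	1	0	0	0	0.80
hsa-miR-199a-5p	-0.66	RPL15	1	0	WDFY3-AS2	-0.63	1	0	0	0	0.62
hsa-miR-199a-5p	-0.63	ZNF415	0	1	LINC00518	-0.66	1	0	0	0	0.72
hsa-miR-195-5p	-0.66	TPRG1L	1	0	LINC01128	-0.66	0	0	0	1	0.82
hsa-miR-508-3p	-0.61	GPR176	0	1	HCP5	-0.70	1	0	0	0	0.63
hsa-miR-195-5p	-0.65	BSDC1	1	0	LINC01128	-0.67	0	0	0	1	0.61
hsa-miR-195-5p	-0.65	CTNNBIP1	1	0	LINC01128	-0.67	0	0	0	1	0.72
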