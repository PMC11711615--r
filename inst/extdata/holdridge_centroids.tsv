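biome_id	biome_code	biome_name	life_zone	APP	ABT	PER
1	T	Tundra	Polar Desert	88.39	0.00	0.71
1	T	Tundra	Polar Desert	176.78	0.00	0.35
1	T	Tundra	Polar Desert	353.55	0.00	0.18
2	CP	Cold Parklands	Dry Tundra	88.39	2.12	1.41
2	CP	Cold Parklands	Boreal Desert	88.39	4.24	2.83
2	CP	Cold Parklands	Dry Scrub	176.78	4.24	1.41
3	FT	Forest Tundra	Moist Tundra	176.78	2.12	0.71
3	FT	Forest Tundra	Wet Tundra	353.55	2.12	0.35
3	FT	Forest Tundra	Rain Tundra	707.11	2.12	0.18
4	BF	Boreal Forest	Moist Forest	353.55	4.24	0.71
4	BF	Boreal Forest	Wet Forest	707.11	4.24	0.35
4	BF	Boreal Forest	Rain Forest	1414.21	4.24	0.18
5	CD	Cool Desert	Montane Desert	88.39	8.49	5.66
5	CD	Cool Desert	Desert Scrub	176.78	8.49	2.83
6	ST	Steppe	Steppe	353.55	8.49	1.41
7	CF	Cool Forest	Moist Forest	707.11	8.49	0.71
7	CF	Cool Forest	Wet Forest	1414.21	8.49	0.35
7	CF	Cool Forest	Rain Forest	2828.43	8.49	0.18
8	HD	Hot Desert	Subtropical Desert	88.39	16.97	11.31
8	HD	Hot Desert	Desert Scrub	176.78	16.97	5.66
8	HD	Hot Desert	Tropical Desert	88.39	26.83	22.63
8	HD	Hot Desert	Desert Scrub	176.78	26.83	11.31
9	CH	Chaparral	Thorn Steppe/Woodland	353.55	16.97	2.83
9	CH	Chaparral	Dry Forest	707.11	16.97	1.41
10	TF	Temperate Forest	Moist Forest	1414.21	16.97	0.71
10	TF	Temperate Forest	Wet Forest	2828.43	16.97	0.35
10	TF	Temperate Forest	Rain Forest	5656.85	16.97	0.18
11	TS	Tropical Semi-arid	Thorn Woodland	353.55	26.83	5.66
11	TS	Tropical Semi-arid	Very Dry Forest	707.11	26.83	2.83
12	TDR	Tropical Dry Forest	Dry Forest	1414.21	26.83	1.41
13	TRF	Tropical Rain Forest	Moist Forest	2828.43	26.83	0.71
13	TRF	Tropical Rain Forest	Wet Forest	5656.85	26.83	0.35
13	TRF	Tropical Rain Forest	Rain Forest	11313.71	26.83	0.18
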