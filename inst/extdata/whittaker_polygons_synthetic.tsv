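biome_id	biome_name	vertex	MAT	APP_cm
1	Tundra	1	-15	0
1	Tundra	2	-5	0
1	Tundra	3	-5	35
1	Tundra	4	-15	15
2	Boreal forest	1	-5	0
2	Boreal forest	2	3	0
2	Boreal forest	3	3	110
2	Boreal forest	4	-5	35
3	Temperate grassland/desert	1	3	0
3	Temperate grassland/desert	2	18	0
3	Temperate grassland/desert	3	18	22
3	Temperate grassland/desert	4	3	40
4	Woodland/shrubland	1	3	40
4	Woodland/shrubland	2	18	22
4	Woodland/shrubland	3	22	55
4	Woodland/shrubland	4	22	90
4	Woodland/shrubland	5	3	65
5	Temperate seasonal forest	1	3	65
5	Temperate seasonal forest	2	22	90
5	Temperate seasonal forest	3	22	210
5	Temperate seasonal forest	4	3	110
6	Temperate rain forest	1	3	110
6	Temperate rain forest	2	22	210
6	Temperate rain forest	3	22	300
6	Temperate rain forest	4	3	160
7	Tropical seasonal forest/savanna	1	22	55
7	Tropical seasonal forest/savanna	2	30	45
7	Tropical seasonal forest/savanna	3	30	240
7	Tropical seasonal forest/savanna	4	22	120
8	Tropical rain forest	1	22	120
8	Tropical rain forest	2	30	240
8	Tropical rain forest	3	30	450
8	Tropical rain forest	4	22	450
9	Subtropical desert	1	18	0
9	Subtropical desert	2	30	0
9	Subtropical desert	3	30	45
9	Subtropical desert	4	22	55
9	Subtropical desert	5	18	22
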