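trait	dataset	method	linkage_group	interval_start	interval_end	peak_cm	snp_id	snp_cm	snp_mbp	pve
cracking	2019	pba	1	41	47	44	NA	NA	NA	2
cracking	2019	pba	5	0	37	34	NA	NA	NA	7.6
cracking	2019	pba	7	49	74	55	NA	NA	NA	8.1
cracking	2019	pba	8	38	59	39	NA	NA	NA	2
cracking	2020	pba	1	44	72	51	NA	NA	NA	12.6
cracking	2020	blink	1	NA	NA	NA	ss490546566	44.95	15.1	15.1
cracking	2020	blink	3	NA	NA	NA	ss490551560	40.87	15.9	4.8
cracking	2020	pba	5	31	53	47	NA	NA	NA	11.2
cracking	2020	blink	5	NA	NA	NA	ss490559206	48.22	15.5	11.9
cracking	2020	blink	7	NA	NA	NA	ss490550511	16.8	10.7	6.2
cracking	2020	blink	8	NA	NA	NA	ss490558540	59.96	18.1	4.2
cracking	multiyear	pba	1	44	55	45	NA	NA	NA	10.5
cracking	multiyear	blink	1	NA	NA	NA	ss490546611	45.51	16	12.7
cracking	multiyear	blink	3	NA	NA	NA	ss490551560	40.87	15.9	3.6
cracking	multiyear	pba	5	2	53	48	NA	NA	NA	8.1
cracking	multiyear	blink	5	NA	NA	NA	ss490559206	48.22	15.5	13.8
cracking	multiyear	pba	7	49	74	56	NA	NA	NA	3.5
cracking	multiyear	pba	8	48	62	55	NA	NA	NA	2.3
cracking	multiyear	blink	8	NA	NA	NA	ss490558540	59.96	18.1	6.6
firmness	2020	pba	1	45	70	48	NA	NA	NA	15.6
firmness	2020	blink	1	NA	NA	NA	ss490558902	47.55	17.6	8.8
firmness	2020	blink	1	NA	NA	NA	ss490548183	115.11	38	0.1
firmness	2020	blink	2	NA	NA	NA	ss490559045	60.16	25.7	0.1
firmness	2020	pba	3	50	66	62	NA	NA	NA	7.9
firmness	2020	blink	3	NA	NA	NA	ss490551714	49	18.6	10.1
firmness	2020	pba	4	0	13	9	NA	NA	NA	6.1
firmness	2020	blink	4	NA	NA	NA	ss490552495	8.88	3.4	0.1
firmness	2020	blink	4	NA	NA	NA	ss490552931	34.17	11.5	9.5
firmness	2020	blink	6	NA	NA	NA	ss490555068	9.75	3.1	9.7
firmness	2020	blink	6	NA	NA	NA	ss490555531	43.67	9.9	3.4
firmness	multiyear	blink	1	NA	NA	NA	ss490545817	13.27	6	2.9
firmness	multiyear	pba	1	34	70	48	NA	NA	NA	21.8
firmness	multiyear	blink	1	NA	NA	NA	ss490546574	45.05	15.3	19.2
firmness	multiyear	blink	3	NA	NA	NA	ss490551234	21.59	4.5	6
firmness	multiyear	pba	3	53	66	62	NA	NA	NA	9.1
firmness	multiyear	blink	3	NA	NA	NA	ss490551889	60.92	21	1.7
firmness	multiyear	blink	6	NA	NA	NA	ss490555475	30.69	8.6	4.2
firmness	multiyear	blink	6	NA	NA	NA	ss490555481	31.64	8.7	0.1
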