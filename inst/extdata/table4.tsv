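row_id	genotype	neuron	pos1	pos2	pos3	pos4	pos5	n	comparison_target	position	printed_p
lq61_AQR	etr-1(lq61)	AQR	85	12	2	0	1	100			
lq61_PQR	etr-1(lq61)	PQR	3	5	4	0	88	100			
egl20gk_AQR	egl-20(gk453010)	AQR	99	1	0	0	0	100			
egl20gk_PQR	egl-20(gk453010)	PQR	94	5	0	1	0	100			
egl20n585_AQR	egl-20(n585)	AQR	100	0	0	0	0	100			
egl20n585_PQR	egl-20(n585)	PQR	97	2	1	0	0	100			
egl20mu39_AQR	egl-20(mu39)	AQR	94	6	0	0	0	100			
egl20mu39_PQR	egl-20(mu39)	PQR	36	7	2	3	52	100	egl20gk_PQR;egl20n585_PQR	1	< 0.001
cwn1_AQR	cwn-1(ok546)	AQR	71	23	6	0	0	100			
cwn1_PQR	cwn-1(ok546)	PQR	0	0	0	0	100	100			
cwn2_AQR	cwn-2(ok895)	AQR	91	9	0	0	0	100			
cwn2_PQR	cwn-2(ok895)	PQR	0	0	0	4	96	100			
lin44_AQR	lin-44(e1792)	AQR	99	1	0	0	0	100			
lin44_PQR	lin-44(e1792)	PQR	0	0	0	0	100	100			
cwn1egl20_AQR	cwn-1(ok546); egl-20(n585)	AQR	5	23	35	34	3	100	cwn1_AQR	1	< 0.001
cwn1egl20_PQR	cwn-1(ok546); egl-20(n585)	PQR	0	12	34	51	2	99	egl20gk_PQR;egl20n585_PQR	1	< 0.001
cwn1cwn2_AQR	cwn-1(ok546); cwn-2(ok895)	AQR	36	57	6	1	0	100	additive:cwn1_AQR+cwn2_AQR	1	< 0.001
cwn1cwn2_PQR	cwn-1(ok546); cwn-2(ok895)	PQR	0	0	0	0	100	100			
lin44egl20_AQR	lin-44(n1792); egl-20(gk453010)	AQR	88	12	0	0	0	100			
lin44egl20_PQR	lin-44(n1792); egl-20(gk453010)	PQR	61	30	7	0	2	100	egl20gk_PQR;egl20n585_PQR	1	< 0.001
egl20cwn2_AQR	egl-20(n585) cwn-2(ok895)	AQR	16	67	17	0	0	100			
egl20cwn2_PQR	egl-20(n585) cwn-2(ok895)	PQR	13	74	13	0	0	100			
egl20cwn2cwn1_AQR	egl-20(n585) cwn-2(ok895); cwn-1(ok546)	AQR	21	70	8	1	0	100			
egl20cwn2cwn1_PQR	egl-20(n585) cwn-2(ok895); cwn-1(ok546)	PQR	24	54	21	1	0	100			
etr1egl20gk_AQR	etr-1(lq61); egl-20(gk453010)	AQR	87	11	1	1	0	100			
etr1egl20gk_PQR	etr-1(lq61); egl-20(gk453010)	PQR	71	20	8	0	1	100	egl20gk_PQR;egl20n585_PQR	1	< 0.001
etr1mu39_AQR	etr-1(lq61); egl-20(mu39)	AQR	69	29	9	1	0	108			
etr1mu39_PQR	etr-1(lq61); egl-20(mu39)	PQR	4	4	3	12	77	100	egl20mu39_PQR	1	< 0.001
etr1cwn2_AQR	etr-1(lq61); cwn-2(ok895)	AQR	56	35	7	0	2	100	additive:lq61_AQR+cwn2_AQR	1	0.003
etr1cwn2_PQR	etr-1(lq61); cwn-2(ok895)	PQR	3	1	2	11	83	100			
etr1lin44_AQR	etr-1(lq61); lin-44(e1792)	AQR	81	16	3	0	0	100			
etr1lin44_PQR	etr-1(lq61); lin-44(e1792)	PQR	0	1	1	3	95	100			
etr1triple_AQR	etr-1(lq61); egl-20(n585) cwn-2(ok895)	AQR	41	40	15	4	0	100	egl20cwn2_AQR	1	< 0.001
etr1triple_PQR	etr-1(lq61); egl-20(n585) cwn-2(ok895)	PQR	43	34	13	10	0	100	egl20cwn2_PQR	1	< 0.001
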