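row_id	genotype	neuron	pos1	pos2	pos3	pos4	pos5	n	comparison_target	position	printed_p
wt_AQR	+/+	AQR	100	0	0	0	0	100			
wt_PQR	+/+	PQR	0	0	0	0	100	100			
lq61_AQR	etr-1(lq61)	AQR	85	12	2	0	1	100			
lq61_PQR	etr-1(lq61)	PQR	3	5	4	0	88	100			
lq133_AQR	etr-1(lq133)	AQR	75	19	13	3	0	110			
lq133_PQR	etr-1(lq133)	PQR	1	1	5	10	82	99			
lqIs327_AQR	lqIs327[etr-1(BWMCRISPR)]	AQR	86	13	1	0	0	100			
lqIs327_PQR	lqIs327[etr-1(BWMCRISPR)]	PQR	1	0	2	1	96	100			
lqEx817_AQR	etr-1(lq61); lqEx817[etr-1(+)]	AQR	97	2	0	0	1	100	lq61_AQR	1	< 0.01
lqEx817_PQR	etr-1(lq61); lqEx817[etr-1(+)]	PQR	0	0	0	0	100	100	lq61_PQR	5	< 0.01
lqEx818_AQR	etr-1(lq61); lqEx818[etr-1(+)]	AQR	98	2	0	0	0	100	lq61_AQR	1	< 0.01
lqEx818_PQR	etr-1(lq61); lqEx818[etr-1(+)]	PQR	0	0	0	0	100	100	lq61_PQR	5	< 0.01
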