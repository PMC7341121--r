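row_id	genotype	neuron	pos1	pos2	pos3	pos4	pos5	n	comparison_target	position	printed_p
Ex912_AQR	etr-1(lq61); lqEx912	AQR	85	11	0	2	1	99	c912_AQR	1	NS
c912_AQR	etr-1(lq61) no Ex (912)	AQR	84	14	0	0	2	100			
Ex912_PQR	etr-1(lq61); lqEx912	PQR	0	0	0	9	91	100	c912_PQR	5	NS
c912_PQR	etr-1(lq61) no Ex (912)	PQR	0	0	0	10	90	100			
Ex913_AQR	etr-1(lq61); lqEx913	AQR	88	7	1	2	2	100	c913_AQR	1	NS
c913_AQR	etr-1(lq61) no Ex (913)	AQR	85	10	1	1	3	100			
Ex913_PQR	etr-1(lq61); lqEx913	PQR	0	0	0	11	89	100	c913_PQR	5	NS
c913_PQR	etr-1(lq61) no Ex (913)	PQR	0	0	0	8	92	100			
Ex914_AQR	etr-1(lq61); lqEx914	AQR	87	10	2	1	0	100	c914_AQR	1	NS
c914_AQR	etr-1(lq61) no Ex (914)	AQR	83	13	2	2	0	100			
Ex914_PQR	etr-1(lq61); lqEx914	PQR	1	0	5	4	90	100	c914_PQR	5	NS
c914_PQR	etr-1(lq61) no Ex (914)	PQR	1	1	3	6	89	100			
Ex944_AQR	etr-1(lq61); lqEx944	AQR	97	0	0	0	0	97	c944_AQR	1	< 0.001
c944_AQR	etr-1(lq61) no Ex (944)	AQR	70	22	5	1	2	100			
Ex944_PQR	etr-1(lq61); lqEx944	PQR	2	0	0	0	95	97	c944_PQR	5	< 0.01
c944_PQR	etr-1(lq61) no Ex (944)	PQR	2	1	3	7	87	100			
Ex945_AQR	etr-1(lq61); lqEx945	AQR	86	14	0	0	0	100	c945_AQR	1	0.051
c945_AQR	etr-1(lq61) no Ex (945)	AQR	74	24	1	1	0	100			
Ex945_PQR	etr-1(lq61); lqEx945	PQR	0	0	0	2	98	100	c945_PQR	5	0.010
c945_PQR	etr-1(lq61) no Ex (945)	PQR	4	3	0	5	88	100			
Ex946_AQR	etr-1(lq61); lqEx946	AQR	94	6	0	0	0	100	c946_AQR	1	0.023
c946_AQR	etr-1(lq61) no Ex (946)	AQR	81	14	2	1	2	100			
Ex946_PQR	etr-1(lq61); lqEx946	PQR	0	0	0	1	99	100	c946_PQR	5	NS
c946_PQR	etr-1(lq61) no Ex (946)	PQR	1	0	0	0	99	100			
Ex947_AQR	etr-1(lq61); lqEx947	AQR	98	3	0	0	0	101	c947_AQR	1	< 0.001
c947_AQR	etr-1(lq61) no Ex (947)	AQR	79	14	6	0	1	100			
Ex947_PQR	etr-1(lq61); lqEx947	PQR	1	0	0	0	100	101	c947_PQR	5	0.065
c947_PQR	etr-1(lq61) no Ex (947)	PQR	1	1	0	4	94	100			
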