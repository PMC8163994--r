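subject	age_y	laterality	duration_y	thi	origin	hl_db
T1	56	B	1	26	W	34
T3	43	B	25	8	AR	14
T4	38	B	15	26	AR	20
T5	59	B	25	22	AR	46
T6	28	B	10	8	M	8
T7	42	B	2	14	AR	18
T8	43	B	14	32	AR	18
T10	42	B	18	24	M&AR	25
T11	51	L	10	44	AR	31
T12	40	R	16	18	AR	10
T16	26	L	1	12	AR	25
T17	60	B	17	12	AR	23
T18	24	B	12	6	M	6
T19	25	B	16	4	M	12
T24	41	R	2	12	M	22
T28	49	R	0.5	12	AR	23
T30	57	B	10	6	W	29
T35	51	L	10	16	M	9
T37	33	B	15	6	AR	11
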