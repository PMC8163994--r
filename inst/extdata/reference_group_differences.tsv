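metric	bundle	min_p_uncorrected	segment	t	d	power
afd	IFO_right	6.70e-08	17	-6.764	2.255	0.980
afd	POPT_left	8.32e-07	10	-5.942	1.981	0.907
afd	UF_right	4.95e-09	62	-7.632	2.544	0.998
afd	T_PAR_left	1.63e-08	11	-7.233	2.411	0.993
afd	AR_right	4.70e-05	29	4.623	1.541	0.554
afd	AR_left	0.00037	22	-3.930	1.310	0.312
peak	ATR_right	4.48e-06	14	5.394	1.798	0.802
peak	IFO_right	1.6e-09	17	-8.017	2.672	0.999
peak	UF_right	8.02e-08	57	-6.705	2.235	0.979
peak	T_PAR_left	2.23e-07	9	-6.371	2.124	0.958
fa	AR_right	1.30e-05	34	5.037	1.679	0.702
fa	IFO_right	1.64e-08	17	-7.231	2.410	0.994
fa	OR_left	3.10e-08	51	7.018	2.339	0.990
fa	POPT_left	2.22e-06	10	-5.622	1.874	0.855
fa	STR_left	9.53e-06	13	-5.149	1.716	0.736
fa	UF_right	1.86e-06	62	-5.680	1.893	0.867
fa	T_PAR_left	6.50e-08	9	-6.775	2.258	0.982
fa	T_OCC_left	2.44e-08	50	7.099	2.366	0.991
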