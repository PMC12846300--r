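protein_id	hit_mass	hit_score	protein_mw	protein_pi	protein_score	pep_count	av_ratio
P00450|CERU_HUMAN	122983	524	115398.4	5.43	400	33	4.21
P01023|A2MG_HUMAN	164600	591	163174.9	6	367	42	3.06
P01024|CO3_HUMAN	188585	256	187029.9	6.02	58	17	4.22
P01009|A1AT_HUMAN	46878	1076	44222.7	5.37	389	22	3.47
P13671|CO6_HUMAN	108425	379	104776	6.31	72	17	3.78
P04217|A1BG_HUMAN	54809	414	51908.4	5.65	192	17	4.36
P02765|FETUA_HUMAN	40098	462	39299.7	5.43	71	7	-2.86
P00739|HPTR_HUMAN	39496	252	38786.6	6.67	153	15	2.95
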