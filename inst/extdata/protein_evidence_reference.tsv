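protein_id	n_peptides_S	n_peptides_total	ratio_peptides_S	S_max_peptides
P00450|CERU_HUMAN	2	8	25	3.2944
P01008|ANT3_HUMAN	1	3	33.333	2.3487
P01011|AACT_HUMAN	3	4	75	2.6915
P01019|ANGT_HUMAN	1	3	33.333	2.3621
P01023|A2MG_HUMAN	6	8	75	2.8357
P01024|CO3_HUMAN	9	16	56.25	2.8358
P01031|CO5_HUMAN	1	2	50	2.7788
P02753|RETBP_HUMAN	1	2	50	2.337
P02774|VTDB_HUMAN	2	4	50	2.8825
P02790|HEMO_HUMAN	2	3	66.667	2.3691
P04004|VTNC_HUMAN	1	2	50	2.6691
P04114|APOB_HUMAN	4	5	80	2.4843
P05546|HEP2_HUMAN	1	2	50	2.4736
P06727|APOA4_HUMAN	2	2	100	2.3306
P08603|CFAH_HUMAN	3	3	100	2.363
P0C0L4|CO4A_HUMAN	6	11	54.545	2.3616
P10909|CLUS_HUMAN	1	3	33.333	2.4345
P13645|K1C10_HUMAN	3	4	75	2.3712
P19823|ITIH2_HUMAN	2	4	50	2.2836
P19827|ITIH1_HUMAN	1	3	33.333	2.0629
P35858|ALS_HUMAN	1	2	50	2.3352
Q14624|ITIH4_HUMAN	2	3	66.667	2.905
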