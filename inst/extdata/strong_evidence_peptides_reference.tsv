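protein_id	peptide
P00450|CERU_HUMAN	K.AETGDKVYVHLK.N
P00450|CERU_HUMAN	K.VNKDDEEFIESNK.M
P01011|AACT_HUMAN	K.EQLSLLDRFTEDAKR.L
P01011|AACT_HUMAN	K.ITLLSALVETR.T
P01011|AACT_HUMAN	R.EIGELYLPK.F
P01023|A2MG_HUMAN	R.TEHPFTVEEFVLPK.F
P01023|A2MG_HUMAN	R.IAQWQSFQLEGGLK.Q
P01023|A2MG_HUMAN	K.FEVQVTVPK.I
P01023|A2MG_HUMAN	K.YGAATFTR.T
P01023|A2MG_HUMAN	K.QQNAQGGFSSTQDTVVALHALSK.Y
P01023|A2MG_HUMAN	K.HYDGSYSTFGER.Y
P01024|CO3_HUMAN	K.LSINTHPSQKPLSITVR.T
P01024|CO3_HUMAN	R.TKKQELSEAEQATR.T
P01024|CO3_HUMAN	K.KLVLSSEK.T
P01024|CO3_HUMAN	R.IPIEDGSGEVVLSR.K
P01024|CO3_HUMAN	R.VPVAVQGEDTVQSLTQGDGVAK.L
P01024|CO3_HUMAN	K.SDDKVTLEERLDK.A
P01024|CO3_HUMAN	K.RIPIEDGSGEVVLSR.K
P01024|CO3_HUMAN	R.HQQTVTIPPK.S
P01024|CO3_HUMAN	K.LMNIFLK.D
P02774|VTDB_HUMAN	K.HLSLLTTLSNR.V
P02774|VTDB_HUMAN	K.YTFELSR.R
P02790|HEMO_HUMAN	K.GDKVWVYPPEKK.E
P02790|HEMO_HUMAN	K.GGYTLVSGYPK.R
P04114|APOB_HUMAN	R.NLQNNAEWVYQGAIR.Q
P04114|APOB_HUMAN	R.TSSFALNLPTLPEVK.F
P04114|APOB_HUMAN	R.EFQVPTFTIPK.L
P04114|APOB_HUMAN	K.IEGNLIFDPNNYLPK.E
P06727|APOA4_HUMAN	K.SELTQQLNALFQDK.L
P06727|APOA4_HUMAN	K.SLAELGGHLDQQVEEFR.R
P08603|CFAH_HUMAN	K.SPDVINGSPISQK.I
P08603|CFAH_HUMAN	K.SSNLIILEEHLK.N
P08603|CFAH_HUMAN	K.IDVHLVPDR.K
P0C0L4|CO4A_HUMAN	R.GPEVQLVAHSPWLK.D
P0C0L4|CO4A_HUMAN	K.DHAVDLIQK.G
P0C0L4|CO4A_HUMAN	R.GSFEFPVGDAVSK.V
P0C0L4|CO4A_HUMAN	K.ADGSYAAWLSR.D
P0C0L4|CO4A_HUMAN	R.GLQDEDGYR.M
P0C0L4|CO4A_HUMAN	K.YVLPNFEVK.I
P13645|K1C10_HUMAN	K.SKELTTEIDNNIEQISSYK.S
P13645|K1C10_HUMAN	R.SQYEQLAEQNRK.D
P13645|K1C10_HUMAN	R.ALEESNYELEGK.I
P19823|ITIH2_HUMAN	K.RLSNENHGIAQR.I
P19823|ITIH2_HUMAN	K.IQPSGGTNINEALLR.A
Q14624|ITIH4_HUMAN	R.GPDVLTATVSGK.L
Q14624|ITIH4_HUMAN	R.NVHSGSTFFK.Y
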