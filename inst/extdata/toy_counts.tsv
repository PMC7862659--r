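otu_id	A_T2_PS_1	A_T2_PS_2	A_T2_PS_3	A_T6_PS_1	A_T6_PS_2	A_T6_PS_3	A_T7_PS_1	A_T7_PS_2	A_T7_PS_3
OTU_A	6	6	0	0	0	0	0	0	0
OTU_B	10	0	0	10	0	0	10	0	0
OTU_C	1	1	1	0	0	0	0	0	0
OTU_D	9983	9993	9999	9990	10000	10000	9990	10000	10000
OTU_E	0	0	0	0	0	0	0	0	0
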