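individual	L1	L2	L3	L4	L5	L6	S1	S2	S3	S4	S5	S6
i01	0	1	1	1	0	1	0	0	0	0	0	0
i02	1	1	1	0	NA	1	1	1	1	1	1	1
i03	1	0	0	0	1	1	1	1	1	1	1	1
i04	2	0	1	0	NA	1	2	2	2	2	2	2
i05	0	1	1	0	2	1	0	0	0	0	0	0
i06	1	1	0	0	NA	1	1	1	1	1	1	1
i07	2	1	0	0	0	1	2	2	2	2	2	2
i08	1	1	1	0	NA	1	1	1	1	1	1	1
i09	1	2	1	0	1	1	1	1	1	1	1	1
i10	0	0	2	0	2	1	0	0	0	0	0	0
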