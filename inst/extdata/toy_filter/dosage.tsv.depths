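individual	L1	L2	L3	L4	L5	L6	S1	S2	S3	S4	S5	S6
i01	20,0	3,2	13,4	10,10	20,0	10,10	20,0	20,0	20,0	20,0	20,0	20,0
i02	10,10	4,2	9,2	20,0	0,0	10,10	10,10	10,10	10,10	10,10	10,10	10,10
i03	10,10	2,2	20,0	20,0	10,10	10,10	10,10	10,10	10,10	10,10	10,10	10,10
i04	0,20	20,0	10,10	20,0	0,0	10,10	0,20	0,20	0,20	0,20	0,20	0,20
i05	20,0	10,10	10,10	20,0	0,20	10,10	20,0	20,0	20,0	20,0	20,0	20,0
i06	10,10	10,10	20,0	20,0	0,0	10,10	10,10	10,10	10,10	10,10	10,10	10,10
i07	0,20	10,10	20,0	20,0	20,0	10,10	0,20	0,20	0,20	0,20	0,20	0,20
i08	10,10	10,10	10,10	20,0	0,0	10,10	10,10	10,10	10,10	10,10	10,10	10,10
i09	10,10	0,20	10,10	20,0	10,10	10,10	10,10	10,10	10,10	10,10	10,10	10,10
i10	20,0	20,0	0,20	20,0	0,20	10,10	20,0	20,0	20,0	20,0	20,0	20,0
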