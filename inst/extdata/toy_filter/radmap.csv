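snp,rad
L1,r1
L2,r1
L3,r2
L4,r3
L5,r4
L6,r5
S1,rbig
S2,rbig
S3,rbig
S4,rbig
S5,rbig
S6,rbig
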