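sample,dose
S1,12.50
S2,12.50
S3,12.50
S4,12.50
S5,12.50
S6,8.50
S7,11.38
S8,13.45
S9,4.02
S10,5.50
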