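sample,A,B,C,D,E,F,G,H,I,J
S1,7.2004,5.6804,3.7543,2.5943,0.6630,0.4603,0.0000,0.3326,0.0000,0.5606
S2,2.7394,2.3243,7.5994,5.3110,0.4480,0.3251,0.1446,0.0000,0.2813,0.0642
S3,5.7446,4.2589,9.3531,6.0569,0.7114,0.4444,0.0000,0.0000,0.0000,0.5647
S4,3.5665,2.7048,9.1671,5.7693,0.5939,0.4252,0.4210,0.1304,0.4488,0.3111
S5,4.0388,3.1699,8.5072,5.4610,0.5016,0.3530,0.2148,0.0984,0.3069,0.3666
S6,0.2684,1.2157,0.4978,2.6316,0.3686,2.5870,0.2232,0.0000,0.0000,0.0000
S7,0.2376,0.0000,6.5026,6.5026,1.8175,2.0621,0.2444,0.0000,0.0000,0.0000
S8,0.8617,0.0000,1.5864,0.0000,11.4816,0.7648,0.0000,0.0000,0.0000,0.0000
S9,0.0000,0.0000,0.0000,0.0000,1.8821,9.5694,0.0000,0.0000,0.0000,0.0000
S10,0.3785,0.0000,0.6717,0.0000,2.3061,0.5752,0.0000,0.0000,0.0000,0.0000
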