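characteristic,count,total
G3,82,244
MVI,139,244
major_hepatectomy,128,244
solitary,206,244
pattern_1,151,244
pattern_2,61,244
pattern_3,32,244
ca19_9_ge_55,74,244
hbv,19,244
hcv,27,244
cirrhosis,26,244
preop_chemo,26,244
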