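"","eog1"
"Fp1",0.589007
"Fp2",0.590855
"F7",0.148427
"F3",0.238079
"Fz",0.323855
"F4",0.245429
"F8",0.156095
"T3",0.046763
"C3",0.087928
"Cz",0.106106
"C4",0.087869
"T4",0.047613
"T5",0.030772
"P3",0.036432
"Pz",0.032227
"P4",0.022647
"T6",0.025268
"O1",0.009204
"O2",0.007251
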