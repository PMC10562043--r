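detector,kq_16,kq_8,kq_4
Semiflex T31010,1.004,NA,NA
PinPoint T31014,1.000,1.030,NA
Diode P T60016,1.000,0.981,0.965
Diode E T60017,1.000,0.996,0.985
microDiamond T60019,1.000,1.005,0.993
IBA CC04,1.021,NA,NA
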