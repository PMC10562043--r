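detector,kvol_16,kvol_8,kvol_4,ratio_16,ratio_8,ratio_4
Semiflex T31010,1.006,1.042,1.627,1.000,1.036,1.617
Semiflex 3D T31021,1.005,1.019,1.304,1.000,1.014,1.298
PinPoint T31014,1.005,1.011,1.181,1.000,1.006,1.175
PinPoint 3D T31022,1.003,1.010,1.101,1.000,1.001,1.091
Diode P T60016,1.001,1.000,1.008,1.000,0.999,1.007
Diode E T60017,1.001,1.000,1.008,1.000,0.999,1.007
microDiamond T60019,1.000,1.002,1.021,1.000,1.001,1.020
RAZOR diode,1.001,1.000,1.004,1.000,0.999,1.003
EFD 3G-pSi,1.001,1.001,1.018,1.000,1.000,1.017
EDGE detector,1.004,1.003,1.007,1.000,0.999,1.004
RAZOR chamber,1.003,1.006,1.074,1.000,1.003,1.071
IBA CC04,1.007,1.014,1.156,1.000,1.007,1.147
Exradin W2 1x1,1.003,1.002,1.010,1.000,0.999,1.007
Exradin W2 1x3,1.005,1.005,1.042,1.000,1.000,1.037
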