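name	mz
Hex-2CH2O-H2O	85.028406
Hex-CH2O-2H2O	97.028406
Hex-3H2O	109.028406
HexNAc-2CH2O-H2O	126.054955
Hex-2H2O	127.038971
Fuc-H2O	129.054621
HexNAc-CH2O-2H2O	138.054955
HexNAc-C2H4O2	144.065520
Hex-H2O	145.049535
Fuc	147.065185
Hex	163.060100
HexNAc-2H2O	168.065520
HexNAc-H2O	186.076084
HexNAc	204.086649
NeuAc-2H2O	256.081564
NeuAc-H2O	274.092128
NeuGc-H2O	290.087043
NeuAc	292.102693
NeuGc	308.097608
HexHexNAc-H2O	348.128908
HexNAcFuc	350.144558
HexHexNAc	366.139472
HexNAc2	407.166022
HexHexNAc2	569.218845
NeuAcHexHexNAc	657.234889
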