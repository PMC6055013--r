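country,n_signatories,population,n_es_measures,energy_saved_twh,co2_reduction_mt
BE,4,511164,40,1.304,0.406
BG,5,1889087,52,1.640,0.479
CH,1,354755,8,0.094,0.028
CZ,1,296324,24,0.172,0.068
DE,11,3164633,80,4.576,1.837
DK,1,198401,12,0.356,0.068
EE,1,390369,23,0.473,0.130
ES,38,13111263,822,12.211,4.356
FR,9,9857389,46,0.718,0.129
UK,7,2312872,78,1.787,0.458
EL,1,83640,69,0.051,0.080
HR,3,1022383,93,2.084,0.616
HU,2,1885149,17,1.647,0.419
IT,34,11676675,597,22.499,5.689
LT,1,315165,7,0.377,0.084
LV,2,136115,36,0.147,0.033
NL,2,351640,5,0.208,0.078
PL,3,692953,28,0.184,0.093
PT,8,3802884,420,5.506,1.788
RO,8,1191417,205,1.347,0.616
SE,1,112949,3,0.017,0.008
SI,1,279624,21,1.190,0.390
SK,2,488157,27,1.593,0.374
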