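plant,measured_m3,calculated_m3,detected_m3
1,0.00085,0.00089,0.00091
2,0.00089,0.00089,0.00087
3,0.00055,0.00058,0.00051
4,0.00060,0.00081,0.00069
5,0.00125,0.00104,0.00129
6,0.00100,0.00077,0.00065
7,0.00108,0.00110,0.00104
8,0.00050,0.00048,0.00014
9,0.00125,0.00061,0.00054
10,0.00125,0.00112,0.00114
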