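plant,leaves_visible,measured_la_m2,calculated_la_m2,leaves_detected,detected_la_m2
1,18,0.18,0.16,13,0.09
2,18,0.18,0.18,15,0.16
3,19,0.21,0.22,17,0.20
4,17,0.22,0.24,15,0.22
5,15,0.23,0.19,12,0.22
6,17,0.19,0.17,14,0.15
7,18,0.23,0.20,13,0.19
8,19,0.22,0.25,15,0.22
9,16,0.15,0.15,14,0.16
10,14,0.19,0.18,14,0.19
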