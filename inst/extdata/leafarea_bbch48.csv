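plant,leaves_visible,measured_la_m2,calculated_la_m2,leaves_detected,detected_la_m2
1,13,0.57,0.58,12,0.51
2,15,0.71,0.73,13,0.66
3,14,0.67,0.68,14,0.68
4,16,0.71,0.89,16,0.90
5,11,0.60,0.58,11,0.59
6,15,0.85,0.65,13,0.56
7,13,0.62,0.62,13,0.63
8,15,0.82,0.74,13,0.62
9,12,0.61,0.55,12,0.54
10,15,0.67,0.59,11,0.50
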