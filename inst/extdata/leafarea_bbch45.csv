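plant,leaves_visible,measured_la_m2,calculated_la_m2,leaves_detected,detected_la_m2
1,19,0.70,0.65,16,0.54
2,18,0.69,0.61,17,0.56
3,18,0.65,0.72,16,0.70
4,17,0.59,0.68,14,0.55
5,19,0.79,0.75,16,0.72
6,22,0.80,0.80,17,0.60
7,21,0.88,0.93,19,0.82
8,17,0.42,0.49,13,0.39
9,22,0.91,0.81,13,0.48
10,21,0.91,0.80,21,0.78
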