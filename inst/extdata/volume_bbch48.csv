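plant,measured_m3,calculated_m3,detected_m3
1,0.0018,0.0021,0.0021
2,0.0034,0.0037,0.0038
3,0.0028,0.0031,0.0034
4,0.0031,0.0029,0.0033
5,0.0032,0.0029,0.0029
6,0.0029,0.0031,0.0023
7,0.0022,0.0017,0.0015
8,0.0034,0.0027,0.0016
9,0.0036,0.0031,0.0025
10,0.0022,0.0018,0.0016
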