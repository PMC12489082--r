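actual_radius_mm,xgb_radius_mm,cnn_radius_mm
17.2,17.7,17.0
13.2,12.8,12.6
4.8,6.20,5.6
13.6,13.34,12.7
11.6,13.10,12.1
8.8,9.72,10.1
20.8,18.23,19.7
12.4,12.3,11.8
21.6,23.0,21.2
6.0,5.78,5.6
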