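fd
0.16118
0.15747
0.15313
0.15377
0.05976
0.13276
0.0583
0.14451
0.3694
0.19545
0.09613
0.13792
0.09855
0.08841
0.18479
0.40544
0.07713
0.28059
0.18125
0.17992
0.21569
0.20789
0.1898
0.05605
0.17132
0.24566
0.08548
0.18459
0.16192
0.09505
0.08687
0.11485
0.14705
0.08389
0.20755
0.17188
0.11861
0.19458
0.30989
0.0251
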