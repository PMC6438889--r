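fd
0.38798
0.23068
0.11766
0.12493
0.13531
0.13682
0.16721
0.14087
0.05053
0.13606
0.30346
0.19427
0.21537
0.3018
0.09039
0.06405
0.13637
0.22284
0.06645
0.23926
0.21838
0.08373
0.23923
0.10255
0.08921
0.10534
0.31245
0.17984
0.08815
0.20781
0.1517
0.13535
0.127
0.28158
0.16502
0.06715
0.15174
0.05469
0.18505
0.24219
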