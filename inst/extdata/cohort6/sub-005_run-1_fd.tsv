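fd
0.3176
0.15426
0.11491
0.09181
0.13747
0.15982
0.05919
0.19386
0.15868
0.20487
0.1243
0.15833
0.10265
0.08149
0.24346
0.16151
0.0811
0.08246
0.11427
0.13109
0.09672
0.12586
0.13875
0.11334
0.24225
0.16628
0.10951
0.13033
0.105
0.11142
0.1403
0.09915
0.11289
0.10059
0.04184
0.13935
0.11153
0.11369
0.19458
0.31823
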