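fd
0.10555
0.16177
0.07834
0.07331
0.1872
0.11522
0.12043
0.08476
0.1507
0.27917
0.16659
0.12979
0.14501
0.20073
0.46507
0.18598
0.13222
0.39102
0.20886
0.30128
0.1458
0.34365
0.12642
0.2
0.0869
0.32733
0.12755
0.1999
0.09562
0.11931
0.17722
0.09028
0.24104
0.1091
0.06498
0.28214
0.11833
0.14722
0.17024
0.13852
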