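fd
0.19176
0.17629
0.13915
0.19555
0.20995
0.11857
0.17861
0.11662
0.07924
0.3243
0.12614
0.12859
0.21168
0.18332
0.15738
0.03259
0.14442
0.08627
0.30713
0.17725
0.10465
0.10469
0.13319
0.07902
0.11389
0.09249
0.07316
0.18741
0.17113
0.19117
0.26184
0.05534
0.23761
0.09693
0.11245
0.08553
0.09898
0.15619
0.16463
0.12785
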