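fd
0.09213
0.17853
0.17691
0.11724
0.1877
0.11052
0.09134
0.08914
0.10396
0.16617
0.10864
0.2164
0.13539
0.20941
0.13136
0.17648
0.14045
0.05299
0.23601
0.18539
0.23854
0.15568
0.27686
0.17148
0.19584
0.16654
0.05961
0.08201
0.20849
0.17083
0.09871
0.04546
0.17373
0.23183
0.21346
0.19074
0.04881
0.15299
0.09811
0.13179
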