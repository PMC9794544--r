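"day","stiffness_N_per_mm"
0,0.3099
1,2.3359
2,4.9272
3,7.5854
4,10.7399
5,13.4531
6,16.7462
7,20.0671
8,22.8983
9,23.9796
10,29.8457
11,33.7449
12,37.7096
13,40.0892
14,46.5934
15,48.0584
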