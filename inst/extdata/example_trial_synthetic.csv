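"id","arm","y"
1,0,0.90062472898267
2,0,0.851770447092221
3,0,0.72771517415448
4,0,0.73650214568861
5,0,
6,0,0.705515513485513
7,0,1.30035798873208
8,0,
9,0,-0.979283769996278
10,0,0.793761230872534
11,0,0.786506872009449
12,0,-0.3104631309593
13,0,1.6988848455591
14,0,-0.794593708549281
15,0,
16,1,-1.76540107351778
17,1,0.337794720971754
18,1,1.63086499145889
19,1,0.0444540237395431
20,1,-0.399166315538872
21,1,1.22683890173125
22,1,-0.309440901865235
23,1,0.767085115955233
24,1,-1.23726371053359
25,1,-0.911425135808874
26,1,0.0464487732215129
27,1,-0.53549127536806
28,1,1.86214289325928
29,1,1.41745673697502
30,1,-0.285142161076832
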