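run_id,methanol,ratio,time,od
1,50,30,35,0.4249
2,90,30,35,0.0000
3,50,70,35,0.8700
4,90,70,35,0.4947
5,50,50,20,0.6189
6,90,50,20,0.0000
7,50,50,50,0.6671
8,90,50,50,0.3522
9,70,30,20,0.4575
10,70,70,20,0.8231
11,70,30,50,0.6224
12,70,70,50,0.9318
13,70,50,35,0.8038
14,70,50,35,0.8591
15,70,50,35,0.7822
16,70,50,35,0.8030
17,70,50,35,0.7969
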