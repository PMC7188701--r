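"frame_index","start_s","end_s"
1,0,60
2,60,120
3,120,180
4,180,240
5,240,300
6,300,480
7,480,660
8,660,840
9,840,1020
10,1020,1200
11,1200,1500
12,1500,1800
13,1800,2100
14,2100,2400
15,2400,2700
16,2700,3000
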