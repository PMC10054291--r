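id,x_cm,y_cm
1,0,0
2,0,20
3,20,20
4,20,0
5,20,-20
6,0,-20
7,-20,-20
8,-20,0
9,-20,20
10,0,40
11,40,40
12,40,0
13,40,-40
14,0,-40
15,-40,-40
16,-40,0
17,-40,40
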