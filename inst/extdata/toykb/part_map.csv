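observed_part,appeared_part
1,1
2,9
3,3
4,1
5,5
6,10
7,2
8,8
9,4
10,8
11,6
12,7
13,6
14,10
15,8
16,6
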