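part_id,label
1,full body
2,head
3,eye
4,skin
5,ear
6,nose
7,mouth
8,leg
9,tail
10,back
11,belly
12,urine
13,appetite
14,breathing
15,movement
16,feces
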