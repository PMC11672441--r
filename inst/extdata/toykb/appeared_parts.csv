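part_id,label
1,wound/skin
2,oral
3,eye
4,tail
5,ear
6,digestive system
7,urinary system
8,musculoskeletal
9,neurologic
10,respiratory system
11,immune system
12,circulatory system
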