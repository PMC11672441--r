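id,disease_id,symptom_id
1,1,1
2,1,2
3,2,1
4,2,3
5,3,4
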