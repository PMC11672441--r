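symptom_id,description,observed_part
1,shedding tears,3
2,redness of eyewhite,3
3,itch,1
4,cough,14
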