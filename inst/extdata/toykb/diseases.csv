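disease_id,description,appeared_part
1,glaucoma,3
2,dermatomycosis,1
3,pulmonitis,10
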