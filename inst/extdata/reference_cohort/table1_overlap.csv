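site,frontal,parietal,temporal,occipital,cerebellum,other,unknown
frontal,88,4,4,0,0,1,0
parietal,4,48,2,9,0,2,0
temporal,4,2,20,0,0,0,0
occipital,0,9,0,35,2,2,0
cerebellum,0,0,0,2,61,10,0
other,1,2,0,2,10,17,0
unknown,0,0,0,0,0,0,1
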