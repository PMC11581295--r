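marker,status,frontal,parietal,temporal,occipital,cerebellum
egfr,negative,22,16,4,12,9
egfr,positive,5,1,0,0,2
pdl1,negative,6,9,5,5,6
pdl1,low-positive,4,3,0,5,4
pdl1,positive,17,13,0,7,3
ras,negative,12,8,2,8,3
ras,positive,9,4,1,4,5
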