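subtype,frontal,parietal,temporal,occipital,cerebellum,unknown/other,patients
AC,59,31,14,21,37,2,152
SCC,8,5,5,8,1,0,23
SCLC,6,4,0,2,17,1,28
NSCLC-NOS,15,8,1,4,6,0,31
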