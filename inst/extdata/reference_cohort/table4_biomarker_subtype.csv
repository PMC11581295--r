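marker,status,AC,SCC,NSCLC-NOS,SCLC
egfr,negative,43,7,6,1
egfr,positive,5,0,3,0
pdl1,negative,19,3,4,1
pdl1,low-positive,12,1,2,0
pdl1,positive,29,3,5,0
ras,negative,16,5,6,1
ras,positive,20,1,2,0
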