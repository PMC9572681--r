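stage,S1,S2,S3,S4,S5
S1,49,1,0,0,0
S2,8,37,1,1,3
S3,2,2,40,4,2
S4,0,4,7,33,6
S5,0,2,3,1,44
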