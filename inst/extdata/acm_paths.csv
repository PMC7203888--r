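A,V,C,count
0,0,0,969
1,0,0,245
0,1,0,36
0,0,1,51
1,1,0,27
1,0,1,44
0,1,1,2
1,1,1,1
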