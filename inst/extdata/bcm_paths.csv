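A,V,C,count
0,0,0,387
1,0,0,160
0,1,0,9
0,0,1,25
1,1,0,16
1,0,1,38
0,1,1,1
1,1,1,1
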