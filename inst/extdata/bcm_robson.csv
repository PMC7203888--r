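class,women,caesareans
I,245,20
IIa,107,36
IIb,43,43
III,232,3
IVa,53,6
IVb,11,11
V,99,79
VI,34,34
VII,10,7
VIII,18,15
IX,2,2
X,58,29
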