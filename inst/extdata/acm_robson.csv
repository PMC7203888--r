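class,women,caesareans
I,580,35
IIa,196,49
IIb,41,41
III,527,10
IVa,72,4
IVb,13,13
V,196,165
VI,44,44
VII,33,29
VIII,65,54
IX,11,11
X,127,54
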