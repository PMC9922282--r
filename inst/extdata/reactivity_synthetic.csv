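restype,reactivity
F,60
Y,100
W,150
L,20
I,15
V,12
M,120
H,80
P,10
S,5
T,8
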