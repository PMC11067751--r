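element,radius,spread
H,0.31,0.05
C,0.76,0.01
N,0.71,0.01
O,0.66,0.02
S,1.05,0.03
RE,1.51,0.07
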