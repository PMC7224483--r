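hospital_id,x_km,y_km
A,10,11
B,13,14
C,15,9
D,9,15
E,17,13
F,22,20
G,33,28
H,27,38
I,44,16
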