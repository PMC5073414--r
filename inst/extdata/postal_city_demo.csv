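prefix,city
M,TORONTO
M1,SCARBOROUGH
K,EASTERN
K1,OTTAWA
K2,OTTAWA
K7,KINGSTON
L5,MISSISSAUGA
L8,HAMILTON
N2,WATERLOO
N6,LONDON
P3,SUDBURY
P7,THUNDER_BAY
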