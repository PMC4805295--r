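site,class_elevation_only,paired_site
A1,2,
A2,2*,
A3,3,
A4,3,
A5,3,
A6,3,
B1,2,
B2,2,
C1,2*,
C2,2*,
C3,1,
D1,1,
D2,1,
D3,2,
D4,2*,
E1,1,D1
E2,1,C3
E3,2,D3
F1,1,C3
F2,2,D3
G1,2,D3
G2,1,D1
G3,2,D3
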