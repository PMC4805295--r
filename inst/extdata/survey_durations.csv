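site,min_per_day,class_day,min_per_inundation,class_inund,average_class,expected_class
A1,802,1,520,2,1-2,2
A2,296,2*,220,2*,2*,2*
A3,254,2*,219,2*,2*,2*
A4,149,4,209,2*,3,3
A5,118,4,207,2*,3,3
A6,100,4,275,2*,3,4
B1,131,4,221,2*,3,2*
B2,280,2*,214,2*,2*,2*
C1,141,4,225,2*,3,2*
C2,257,2*,196,3,2*-3,2*/3
C3,869,1,477,2,1-2,2*
D1,911,1,504,2,1-2,2
D2,608,2,307,2*,2-2*,2/2*
D3,528,2,231,2*,2-2*,2*/3
D4,76,4,148,3,3-4,4
E1,1060,1,656,1,1,
E2,800,2,406,2*,2-2*,
E3,560,2,318,2*,2-2*,
F1,846,1,408,2*,2,2*
F2,554,2,266,2*,2-2*,3
G1,527,2,278,2*,2-2*,2*
G2,1102,1,614,1,1,
G3,642,2,296,2*,2-2*,3
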