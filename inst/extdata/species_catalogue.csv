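pattern,match,classes
Avicennia alba,species,2
Sonneratia,genus,2
Avicennia,genus,2*
Rhizophora,genus,2*|3
Bruguiera,genus,2*|3|4
Ceriops,genus,3|5
Lumnitzera,genus,4
Acrostichum aureum,species,4
Phoenix paludosa,species,5
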