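location,site,start,end,elevation_cm_msl,distance_m,disturbed,vegetation,planted
A,A1,2007-03-03,2007-05-25,12,18,FALSE,Avicennia alba,
A,A2,2007-03-17,2007-04-14,92,205,FALSE,Avicennia sp.;Rhizophora sp.;Ceriops decandra,
A,A3,2007-03-03,2007-05-25,104,330,FALSE,Rhizophora apiculata;Avicennia marina;Avicennia officinalis,Rhizophora apiculata
A,A4,2007-03-17,2007-04-14,114,330,FALSE,Avicennia sp.;Rhizophora apiculata;Ceriops decandra,
A,A5,2007-03-03,2007-05-25,116,450,FALSE,Avicennia sp.;Rhizophora apiculata;Ceriops decandra,
A,A6,2007-03-03,2007-05-25,121,680,FALSE,Rhizophora apiculata;Acrostichum aureum,Rhizophora apiculata
B,B1,2007-04-21,2007-05-20,46,50,FALSE,Avicennia alba;Sonneratia alba;Rhizophora apiculata,
B,B2,2007-04-21,2007-05-20,35,255,FALSE,Rhizophora apiculata;Bruguiera parviflora;Avicennia marina,
C,C1,2009-11-02,2009-12-05,98,25,FALSE,Avicennia officinalis;Rhizophora stylosa,
C,C2,2009-11-08,2009-12-05,67,20,FALSE,Bruguiera parviflora;Avicennia officinalis;Rhizophora stylosa,
C,C3,2009-11-08,2009-12-05,-18,10,FALSE,Rhizophora stylosa;Avicennia officinalis;Sonneratia caseolaris,
D,D1,2009-12-06,2009-12-29,-40,NA,FALSE,Sonneratia alba,
D,D2,2009-12-06,2009-12-29,-10,35,FALSE,Sonneratia alba;Avicennia officinalis,
D,D3,2009-12-06,2009-12-29,18,55,FALSE,Avicennia officinalis;Bruguiera gymnorhiza;Sonneratia alba,
D,D4,2009-12-06,2009-12-29,89,100,FALSE,Acrostichum aureum,
E,E1,2011-12-20,2012-01-18,-45,1000,TRUE,,
E,E2,2011-12-20,2012-01-18,-19,1000,TRUE,,
E,E3,2011-12-20,2012-01-19,15,1000,TRUE,,
F,F1,2011-12-20,2012-01-17,-23,670,TRUE,Avicennia sp.;Rhizophora sp.,
F,F2,2011-12-20,2012-01-19,20,670,TRUE,Rhizophora sp.,Rhizophora sp.
G,G1,2011-12-20,2012-01-19,23,950,TRUE,Avicennia sp.;Rhizophora sp.,
G,G2,2011-12-20,2012-01-19,-41,950,TRUE,,
G,G3,2011-12-20,2012-01-19,16,950,TRUE,Rhizophora sp.,Rhizophora sp.
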