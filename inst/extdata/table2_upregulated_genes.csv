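gene,fold,common_group
Thbs1,2.75,S1
Rlf,2.74,"A1, C1"
Tnks2,2.7,A1
Rbp1,2.67,"A1, S1, C1"
Nudt21,2.63,C1
Tpm2,2.59,"A1, S1, C1"
Sri,2.38,A1
Dab1,2.35,"A1, C1"
Pmm1,2.25,"A1, C1"
Sf3a3,2.25,"A1, S1, C1"
Dzip1,2.22,"C1, S1"
Nrg2,2.19,"A1, C1"
Capn12,2.17,"A1, S1, C1"
Prkar1b,2.15,S1
Atp1a2,2.12,A1
Hdlbp,2.12,S1
Slc13a3,2.12,A1
Ncapd3,2.12,"A1, S1, C1"
Lima1,2.07,C1
Pla2g15,2.04,"A1, S1"
Ogfrl1,2.03,"A1, C1"
BC024139,2.02,"A1, S1, C1"
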