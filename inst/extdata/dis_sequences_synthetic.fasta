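>DIS_C synthetic stand-in: DIS hairpin with all-C apical loop (29 nt)
GGGCGGUGGUGCCCCCCCGCGUCAGCGCG
>DIS_Gk synthetic stand-in: all-G loop, UCU bulge, 16 bp kinked elongation (65 nt)
GCAUGCAUGACAUAGCUCUGAUCGAUCGAUGGGGGGGCAUCGAUCGAUCGCCAUGUCAUGCAUGC
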