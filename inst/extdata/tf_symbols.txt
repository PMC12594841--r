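ZEB2
TBX21
PRDM1
EOMES
TOX
NR4A1
LEF1
TCF7
BACH2
ID2
ID3
RUNX3
KLF2
FOXO1
STAT4
BATF
IRF4
MYB
NFATC1
BCL6
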