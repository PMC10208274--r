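gene	literature_families
ATP1A2	21
ATP1A3	26
CACNA1A	14
CACNA1S	0
CDK8	0
CHAMP1	6
CLCN1	0
CNR1	0
GFAP	18
HMBS	6
KCNA1	0
KCNJ2	0
KCNJ18	0
MEFV	2
OPRM1	0
OTC	54
PDHA1	0
PNKD	0
POGZ	10
POLG	2
PPM1D	8
PRRT2	0
RYR2	4
SCN1A	0
SCN2A	0
SCN4A	0
SCN9A	0
SCN10A	0
SCN11A	0
SLC1A3	0
SLC2A1	11
TNFRSF1A	0
TRAP1	2
TRPA1	0
TUBB3	9
mtDNA
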