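gene	variant_id	participant_id	category	zygosity	coseg_group
ATP1A2	p.Glu492Lys	1	other	het
CACNA1A	p.Ala454Thr	1	other	het
CACNA1A	p.Ala454Thr	11	other	het
CACNA1A	p.Arg68Gln	76	other	het
CACNA1A	p.Arg2294Pro	74	other	het
CACNA1A	p.Arg2298Pro	43	other	het
CACNA1A	p.Arg2298Pro	75	other	het
CACNA1A	CAG_7	5	other	het
CACNA1A	CAG_7	8	other	het
CACNA1A	CAG_7	27	other	het
CACNA1A	CAG_7	30	other	het
CACNA1A	CAG_7	52	other	hom
CACNA1A	CAG_7	55	other	het
CACNA1A	CAG_7	67	other	het
CACNA1A	CAG_7	76	other	het
CACNA1A	CAG_7	80	other	hom
CACNA1A	CAG_4	31	other	het
CACNA1A	CAG_4	70	other	het
CACNA1A	p.Tyr2228Asn	50	other	het
CACNA1A	p.Arg2135His	46	other	het
CACNA1S	p.Ser516Leu	30	key	het
CACNA1S	p.Thr1335Ser	72	key	het
CACNA1S	p.Thr1354Ser	16	key	het
CACNA1S	p.Val1253Ala	23	key	het
CACNA1S	p.Ala814Thr	69	other	het
CACNA1S	p.Tyr299His	69	other	het
CACNA1S	p.Cys288Gly	32	other	het
CACNA1S	p.Pro1839Ser	14	other	het
CACNA1S	p.Ser1857Asn	43	other	het
CHAMP1	p.Pro406Ser	25	other	het
CLCN1	p.Thr736Ile	68	key	het
GFAP	p.Asp157Asn	48	other	het
GFAP	p.Pro47Leu	35	other	het
GFAP	p.Pro47Leu	76	other	het
KCNJ18	p.Gln407*	37	key	het
MEFV	p.Ala744Ser	53	key	het
MEFV	p.Ile591Thr	65	key	het
MEFV	p.Val726Ala	5	key	het	MEFV_5
MEFV	c.*381T>C	5	key	het	MEFV_5
MEFV	p.Pro369Ser	36	other	het
MEFV	p.Pro369Ser	66	other	het
MEFV	p.Arg408Gln	66	other	het
OPRM1	p.Cys192Phe	2	other	het
OPRM1	p.Cys192Phe	34	other	het
OPRM1	p.Cys192Phe	73	other	het
OPRM1	p.Ser147Cys	53	other	het
OPRM1	p.Ser451Phe	11	other	het
PDHA1	p.Met320Leu	28	other	het
PNKD	p.Glu307Lys	43	other	het
POGZ	p.Cys652Arg	18	key	het
POGZ	p.Phe806Leu	77	key	het
POGZ	p.Lys871Asn	27	other	het
POLG	p.Lys460_Leu463del	74	key	het
POLG	p.Arg42_Gln43insGln	38	other	het
POLG	p.Gly268Ala	9	other	het
POLG	p.Gly268Ala	18	other	het
POLG	p.Gly517Val	38	other	het
POLG	p.Gly517Val	52	other	het
POLG	p.Gly517Val	58	other	het
PPM1D	p.Tyr401fs	56	key	het
PRRT2	p.Pro216Leu	41	other	het
PRRT2	p.Pro216Leu	42	other	het
PRRT2	p.Pro216Leu	54	other	het
RYR2	p.Tyr3459*	54	key	het
RYR2	p.Glu4431Lys	44	key	het
RYR2	p.Gly2094Ser	53	key	het
RYR2	p.Arg3567Cys	9	other	het
RYR2	p.Arg4573His	35	other	het
RYR2	p.Asn4736Asp	34	other	het
RYR2	p.Gly1885Glu	4	other	het
RYR2	p.Ser2829Gly	75	other	het
RYR2	p.Thr1107Met	15	other	het
SCN1A	p.Arg1928Gly	80	key	het
SCN1A	p.Ile1437Val	29	other	het	SCN1A_29
SCN1A	p.Ile1452Val	29	other	het	SCN1A_29
SCN1A	p.Ile1465Val	29	other	het	SCN1A_29
SCN2A	p.Ile403Thr	58	other	het
SCN2A	p.Thr674Ala	58	other	het
SCN4A	p.Ala488Thr	68	key	het
SCN4A	p.His599Arg	61	key	het
SCN4A	p.His599Arg	76	key	het
SCN4A	p.Ser906Thr	63	key	het
SCN4A	p.Arg1408Cys	45	other	het
SCN4A	p.Lys477Arg	49	other	het
SCN4A	p.Thr323Met	50	other	het
SCN4A	p.Ser906Thr	15	other	het
SCN4A	p.Ser906Thr	25	other	het
SCN4A	p.Ser906Thr	52	other	het
SCN4A	p.Ser906Thr	73	other	het
SCN4A	p.Ser906Thr	78	other	het
SCN9A	p.Asn1256Ser	9	key	het
SCN9A	p.Ser802Gly	27	key	het
SCN9A	p.Val1726Phe	7	other	het
SCN9A	p.Val1715Phe	9	other	het
SCN10A	p.Ala123Val	64	key	het
SCN10A	p.Arg14Leu	47	key	het
SCN10A	p.Val1697Ile	27	key	het
SCN11A	p.Gly1736Val	50	other	het
SLC1A3	p.Arg47Gln	77	other	het
TNFRSF1A	p.Arg121Gln	14	key	het
TNFRSF1A	p.Arg121Gln	60	key	het
TNFRSF1A	p.Arg121Gln	68	key	het
TNFRSF1A	p.Pro75Leu	69	other	het
TRAP1	p.Ile253Val	18	key	het
TRAP1	p.Arg128His	60	key	het
TRAP1	p.Arg469Cys	7	other	het
TRAP1	p.Asp685Asn	39	other	het
TRAP1	p.Arg469His	39	other	het
TRAP1	p.Gln165Glu	14	other	het
TRAP1	p.Gly445Ser	3	other	het
TRAP1	p.Ser477_Gly478insAla	3	other	het
TRAP1	p.Ser477_Gly478insAla	76	other	het
TRAP1	p.Tyr444Asn	51	other	het
TRPA1	p.Ala138Ser	49	key	het
TRPA1	p.Met214Thr	52	key	het
TRPA1	p.Asn109Lys	2	other	het
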