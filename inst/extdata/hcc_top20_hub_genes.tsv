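rank	gene
1	CDC20
2	TOP2A
3	CENPF
4	DLGAP5
5	UBE2C
6	ARHGAP11A
7	RACGAP1
8	HIST1H2AJ
9	HIST1H2AH
10	HIST1H2AM
11	HIST1H2AK
12	HIST1H2BO
13	HIST1H4H
14	HIST2H2AB
15	HIST1H2BJ
16	HIST1H2BB
17	HIST1H3E
18	HIST1H2AD
19	HIST1H2BI
20	HIST1H2BL
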