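study_id	authors	platform	n_hub_genes	genes
1	Maddah et al.	Affy.	10	BUB1; DLGAP5; CDCA8; ASPM; POLQ; WDHD1; CENPE; HELLS; TRIP13; DEPDC1
2	Zhao et al.	Affy.	7	CCNA2; CDK1; CCNB1; MAD2L1; RRM2; NDC80; TOP2A
3	Liu et al.	Affy.	10	CYP3A4; AOX1; UGT1A4; UGT1A6; DK1; UGT2B15; C CCNB2; CCNB1; CDC20; MAD2L1
4	Meng et al.	Affy.\Illum.\Agilent	11	CDK1; CDC20; CCNB2; CCNB1; CCNA2; TOP2A; MELK; KIF20A; PBK; TPX2; AURKA
5	Rosli et al.	Affy.	21	CDK1; MAD2L1; TOP2A; CCNA2; CCNB1; CCNB2; KIF11; NCAPG; TTK; AURKA; CDC20; RRM2; NDC80; CENPA; MELKPBK; BUB1B; PRC1; DTL; NUSAP1; KIF2C
6	Zhang et al.	Affy.	10	GMPS; ACACA; KRAS; BCL2; ALB; TGFB1; EGFR; STAT3; ERBB2; CD8A
7	Li et al.	Affy.	5	SPP1; IGF1; LGALS3; COL1A2; LPA
8	Li et al.	Affy.	8	BUB1; CCNA2; BUB1B; CCNB1; CDK1; CDC20; MAD2L1; CCNB2
9	Tian et al.	Affy.\Illum.	5	CDC20; RRM2; TOP2A; AOX1 UBE2C
10	Wan et al.	Agil.	12	GF1; NDC80; IGF2; CDK1; CDCA8; CCNB1; CENPF; BIRC5; NCAPG; CDCA5; SPC25; CENPU
11	Zhu et al.	Affy.	10	CDK1; CCNB1; TOP2A; CDC20; PLK1; CCNB2; BIRC5; FOS; AURKA; AURKB
12	Wang et al.	Affy.	10	TOP2A; ITGA2; CDK1; PLK1; CCNB2; ESR1; AURKA; CCNA2; BUB1; BUB1B
13	Zhou et al.	Affy.\Illum.\Agil.	9	ASPM; CCNB2; AURKA; MELK; CDKN3; NUSAP1; NCAPG; TOP2A; PRC1
14	Zhang et al.	Affy.\Agil.	10	CDK1; AURKA; CCNB1; KIF11; CCNA2; TOP2A; BUB1B; HMMR; TPX2; CDC45
15	Nguyen et al.	Affy.	5	TOP2A; NEK2; RRM2; CCNB1; CDK1
16	Wu et al.	Affy.	8	CDKN3; CCNB1; CDK1; TOP2A; CCNB2; CCNA2; RRM2 PRC1
17	Gui et al.	Agil.	4	MT1X; CAP2; BMI1; TACSTD2
18	Wang et al.	Affy.	10	NDC80; TOP2A; CDK1; AURKA; HMMR; CCNB1; FOXM1; CENPF; PTTG1; CDKN3
19	Zhang et al.	Affy.	10	GMPS; ALB; ACACA; TGFB1; ERBB2; KRAS; BBCL2; STAT3; EGFR; CD8A
20	Bhatt et al.	Illum.	6	DMC1; MSH3; IL10; ALPP; HSD17B7; ZNF223
21	Jiang et al.	Affy.	13	TLR1; TLR4; TLR8; TLR7; RIPK2; FOS; YWHAZ; FOSL2; FASLG; HIF1A; CDK1A; CCL4; DDIT3
22	Zhang et al.	Affy.\Illum.	20	CDK1; CDC20; CCNB2; AURKA; CCNA2; CCNB1; MAD2L1; BUB1B; TOP2A; BUB1; IGF1; ESR1; FTCD; C8A; CYP3A4; CYP2E1; SPP2; F9; TAT; CYP2C9
23	Wu et al.	Affy.	12	TTK; CCNB1; TOP2A; RRM2; PRC1; NCAPG; CDK1; UBE2C; CDKN3; ZWINT; RACGAP1; AURKA
24	Mou et al.	Affy.\Illum.	18	TK1; TOP2A; FOS; CDC20; CCNB2; ESR1; CXCL12; VWF; HMMR; FOXO1; ACSM3; ZIC2; RFC4; TXNRD1; COL4A1; CYP3A4; GNAO1; RAP2A
25	Chen et al.	Affy.	11	RRM2; ECT2; NDC80; ASPM; CDK1; CCNB1; PRC1; KIF20A; TOP2A; DTL; PBK
26	Yu et al.	Affy.	6	TOP2A; CDC6; MAD2L1; CHEK1; CCNB1; UBE2C
27	Kakar et al.	Affy.	10	CDK1; CCNB1; CCNA2; CCNB2; NDC80; BUB1; CDC20; NCAPG; BUB1B; MAD2L1
28	Ji et al.	Affy.\Agil.	10	CDK1; PBK; ASPM; CCNB1; CCNB2; NDC80; AURKA; KIF2C; TPX2; CENPF
29	Zhou et al.	Affy.	15	DTL; RACGAP1; CDK1; CCNB1; ECT2; NEK2; BUB1B; ASPM; HMMR; PBK; TOP2A; RRM2; CDKN3; PRC1; ANLN
30	Qiang et al.	Affy.	10	CDK1; CDC20; CCNB2; BUB1; CCNB1; NDC80; BUB1B; CENPF; NUF2; MAD2L1
31	He et al.	Affy.	4	CDK1; RRM2; PBK; ASPM
32	Zhang et al.	Affy.	10	CCNB1; TOP2A; AURKA; NEK2; NUF2; CENPF; CDKN3; ASPM; PRC1; RACGAP1
33	Wang et al.	Affy.	5	CDK1; CCNB2; CCNB1; TOP2A; MAD2L1
34	Sha et al.	Affy.	14	TOP2A; DTL; HMMR; CCNB1; PBK; NEK2; RACGAP1; CDK1; PRC1; RRM2; BUB1B; ECT2; ANLN; ASPM
35	Chen et al.	Affy.\Illum.\Agil.	10	TOP2A; PRC1; CCNB2; RACGAP1; CDKN3; AURKA; NUSAP1; ASPM; CDCA5; NCAPG
36	Wang et al.	Illum.	10	CDKN3; UBE2C; TOP2A; CDC20; ASPM; PBK; KIF20A; CCNB2; NCAPG; CYP3A4
37	Zhang et al.	Affy.\Agil.	10	NEK2; TOP2A; ANLN; CENPF; CDC20; ASPM; CDK1; ECT2; CCNB1; CCNB2
38	Zhang et al.	Affy.\Illum.	9	ALDH2; CYP2C8; PPTG1; ADH1B; ADH4; CYP2C8; TOP2A; CDC20; CCNB2
39	Hu et al.	Illum.	4	JUN; MYC; EGR1; CDKN1A
40	Li et al.	Affy.	15	TOP2A; CCNB1; CDK1; BUB1; CCNB2; CENPF; TTK; KIF2C; MELK; HMMR; CENPE; PBK; KIF4A; KIF20A; DLGAP5
41	Cao et al.	Affy.\Illum.	5	MCM3; KIF11; PBK; CHEK1; S100A9
42	Zhang et al.	Affy.	10	GMPS; ALB; ACACA; TGFB1; ERBB2; KRAS; BCL2; STAT3; EGFR; CD8A
43	Kim et al.	Affy.	14	ANLN; BUB1B; ASPM; CCNB1; CDKN3; CDK1; ECT2; NEK2; HMMR; PBK; RACGAP1; PRC1; TOP2A; RRM2
44	Jiang et al.	Affy.	9	ANLN; BUB1B; BIRC5; CDC20; CDK1; CDCA5; NCAPG; TOP2A; NEK2
45	Li et al.	Affy.	16	BIRC5; CCNB2; BUB1; CDC20; CDK1; CDC25C; CXCL12; CEP55; KIF20AK; FOS; NUSAP1; RACGAP; KIF2C; SPC24; PRC1; TOP2A
46	Dai et al.	Affy.	20	ANLN; NDC80; DLGAP5; NUSAP1; PBK; RACGAP1; NUF2; BUB1B; ZWINT; CCNB1; DTL; TOP2A; KIF20A; RRM2; CDKN3; PRC1; HMMR; NPY1R; CCL20; CXL12
47	Zhu et al.	Affy.	10	UBE2C; TK; CDK1; NCAPG; RAD51AP1; TOP2A; ASPM; DLGAP5; PBK; NUSAP1
48	Xing et al.	Affy.\Illum.	15	TOP2A; CCNB2; PCNA; AURKA; BUB1; CDKN3; RFC4; CEP55; DLGAP5; PRC1; MCM2; CDC20; TPX2; RACGAP1; MCM4
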