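raw	normalized	note
DK1	CDK1	dropped leading C
BBCL2	BCL2	doubled letter
RACGAP	RACGAP1	truncated suffix
PPTG1	PTTG1	transposed letters
GF1	IGF1	dropped leading I
TK	TK1	truncated suffix; same study cohort as TK1 elsewhere
KIF20AK	KIF20A	trailing stray letter
CXL12	CXCL12	dropped letter
CDK1A	CDKN1A	dropped letter
MELKPBK	MELK;PBK	two symbols fused without separator
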