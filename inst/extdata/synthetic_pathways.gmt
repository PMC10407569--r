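Toll-like receptor signaling	synthetic gene set	IRAK1	TRAF6	TLR4	MYD88	NFKB1	IL6	TNF	CD14
NF-kB signaling	synthetic gene set	NFKB1	RELA	TRAF6	IRAK1	IKBKB	TNF	IL1B
ErbB signaling	synthetic gene set	EGFR	ERBB2	ERBB3	SHC1	GRB2	SOS1	MAPK1
Insulin signaling	synthetic gene set	INSR	IRS1	PIK3CA	AKT1	GSK3B	SLC2A4	PDE3B
TNF signaling	synthetic gene set	TNF	TNFRSF1A	TRAF2	RIPK1	MAP3K7	IL6	CCL2
Neurotrophin signaling	synthetic gene set	NTRK1	NGF	BDNF	NUMB	SHC1	PLCG1
Vesicle transport	synthetic gene set	STX3	SNAP25	VAMP2	STXBP1	RAB27A
Wnt signaling	synthetic gene set	WNT1	CTNNB1	GSK3B	APC	AXIN1	LRP6	TCF7
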