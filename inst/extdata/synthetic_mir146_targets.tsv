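miR_family	target_gene
miR-146	IRAK1
miR-146	TRAF6
miR-146	NUMB
miR-146	STX3
miR-146	CARD10
miR-146	NOVA1
miR-146	SIKE1
miR-146	SORT1
miR-21	PTEN
miR-21	PDCD4
miR-21	SPRY1
let-7	LIN28A
let-7	HMGA2
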