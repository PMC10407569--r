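model	predictor	accuracy	recall	precision	mcc	f_score
NB	miRNAs	0.552	0.7368	0.1296	0.1523	0.2205
DT	miRNAs	0.5385	0.5152	0.9444	0.1553	0.6667
RF	miRNAs	0.5656	0.5638	0.4907	0.1293	0.5248
SVM	miRNAs	0.6063	0.5789	0.7130	0.2220	0.6390
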