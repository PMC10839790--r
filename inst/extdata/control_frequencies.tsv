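locus	allele	frequency	source
A	A*01:01	0.16	controls-mean
A	A*02:01	0.27	controls-mean
A	A*03:01	0.13	controls-mean
A	A*24:02	0.09	controls-mean
A	A*32:01	0.07	controls-mean
B	B*07:02	0.13	controls-mean
B	B*08:01	0.12	controls-mean
B	B*44:02	0.10	controls-mean
C	C*07:01	0.15	controls-mean
C	C*07:02	0.15	controls-mean
DRB1	DRB1*15:01	0.13	controls-mean
DQB1	DQB1*06:02	0.132	controls-mean
DQB1	DQB1*03:01	0.18	controls-mean
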