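locus	allele	g_group
DQA1	DQA1*03:01	DQA1*03:01G
DQA1	DQA1*03:02	DQA1*03:01G
DQA1	DQA1*03:03	DQA1*03:01G
DQA1	DQA1*05:01	DQA1*05:01G
DQA1	DQA1*05:05	DQA1*05:01G
DQB1	DQB1*03:01	DQB1*03:01G
DQB1	DQB1*03:09	DQB1*03:01G
B	B*44:02	B*44:02G
B	B*44:27	B*44:02G
C	C*07:01	C*07:01G
C	C*07:06	C*07:01G
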