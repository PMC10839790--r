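gene	chromosome	start	end	role
HLA-A	chr6	29942470	29945884	HLA-classI
HLA-C	chr6	31268749	31272130	HLA-classI
HLA-B	chr6	31353875	31357188	HLA-classI
TAP2	chr6	32821833	32838739	APP
PSMB8	chr6	32840717	32844679	APP
TAP1	chr6	32845209	32853816	APP
PSMB9	chr6	32854192	32859851	APP
HLA-DRB1	chr6	32578775	32589848	HLA-classII
HLA-DQA1	chr6	32628179	32647062	HLA-classII
HLA-DQB1	chr6	32659467	32668383	HLA-classII
HLA-DPA1	chr6	33064569	33080775	HLA-classII
HLA-DPB1	chr6	33075990	33089696	HLA-classII
B2M	chr15	44711477	44718877	B2M
CIITA	chr16	10866208	10943021	CIITA
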