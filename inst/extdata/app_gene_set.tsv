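gene	set
HLA-A	KEGG-hsa04612
HLA-B	KEGG-hsa04612
HLA-C	KEGG-hsa04612
HLA-E	KEGG-hsa04612
HLA-F	KEGG-hsa04612
HLA-G	KEGG-hsa04612
HLA-DRA	KEGG-hsa04612
HLA-DRB1	KEGG-hsa04612
HLA-DRB3	KEGG-hsa04612
HLA-DRB4	KEGG-hsa04612
HLA-DRB5	KEGG-hsa04612
HLA-DQA1	KEGG-hsa04612
HLA-DQA2	KEGG-hsa04612
HLA-DQB1	KEGG-hsa04612
HLA-DQB2	KEGG-hsa04612
HLA-DPA1	KEGG-hsa04612
HLA-DPB1	KEGG-hsa04612
HLA-DMA	KEGG-hsa04612
HLA-DMB	KEGG-hsa04612
HLA-DOA	KEGG-hsa04612
HLA-DOB	KEGG-hsa04612
B2M	KEGG-hsa04612
TAP1	KEGG-hsa04612
TAP2	KEGG-hsa04612
TAPBP	KEGG-hsa04612
CALR	KEGG-hsa04612
CANX	KEGG-hsa04612
PDIA3	KEGG-hsa04612
PSME1	KEGG-hsa04612
PSME2	KEGG-hsa04612
PSME3	KEGG-hsa04612
HSPA1A	KEGG-hsa04612
HSPA1B	KEGG-hsa04612
HSPA1L	KEGG-hsa04612
HSPA2	KEGG-hsa04612
HSPA4	KEGG-hsa04612
HSPA5	KEGG-hsa04612
HSPA6	KEGG-hsa04612
HSPA8	KEGG-hsa04612
HSP90AA1	KEGG-hsa04612
HSP90AB1	KEGG-hsa04612
CTSB	KEGG-hsa04612
CTSL	KEGG-hsa04612
CTSS	KEGG-hsa04612
IFI30	KEGG-hsa04612
LGMN	KEGG-hsa04612
CD74	KEGG-hsa04612
CIITA	KEGG-hsa04612
NFYA	KEGG-hsa04612
NFYB	KEGG-hsa04612
NFYC	KEGG-hsa04612
RFX5	KEGG-hsa04612
RFXAP	KEGG-hsa04612
RFXANK	KEGG-hsa04612
CREB1	KEGG-hsa04612
CD4	KEGG-hsa04612
CD8A	KEGG-hsa04612
CD8B	KEGG-hsa04612
KLRC1	KEGG-hsa04612
KLRC2	KEGG-hsa04612
KLRC3	KEGG-hsa04612
KLRC4	KEGG-hsa04612
KLRD1	KEGG-hsa04612
KIR2DL1	KEGG-hsa04612
KIR2DL2	KEGG-hsa04612
KIR2DL3	KEGG-hsa04612
KIR2DL4	KEGG-hsa04612
KIR2DL5A	KEGG-hsa04612
KIR2DS1	KEGG-hsa04612
KIR2DS3	KEGG-hsa04612
KIR2DS4	KEGG-hsa04612
KIR2DS5	KEGG-hsa04612
KIR3DL1	KEGG-hsa04612
KIR3DL2	KEGG-hsa04612
KIR3DL3	KEGG-hsa04612
KIR3DS1	KEGG-hsa04612
LTA	KEGG-hsa04612
TNF	KEGG-hsa04612
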