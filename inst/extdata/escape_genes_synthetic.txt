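# Synthetic reconstruction of an 88-gene antigen processing and
# presentation ("escape") list: KEGG hsa04612 members plus ERAP1, ERAP2,
# IRF1, PDIA3, FAS, MEX3B and canonical interferon-pathway escape genes.
# Replace with a curated list for analyses of real cohorts.
HLA-A
HLA-B
HLA-C
HLA-E
HLA-F
HLA-G
B2M
TAP1
TAP2
TAPBP
CALR
CANX
PDIA3
HSPA1A
HSPA1B
HSPA1L
HSPA2
HSPA4
HSPA5
HSPA6
HSPA8
HSP90AA1
HSP90AB1
PSME1
PSME2
PSME3
LGMN
CTSB
CTSL
CTSS
IFI30
KLRC1
KLRC2
KLRC3
KLRC4
KLRD1
KIR2DL1
KIR2DL2
KIR2DL3
KIR2DL4
KIR2DL5A
KIR2DS1
KIR2DS3
KIR2DS4
KIR2DS5
KIR3DL1
KIR3DL2
KIR3DL3
CD74
CD8A
CD8B
CD4
CIITA
RFX5
RFXAP
RFXANK
NFYA
NFYB
NFYC
CREB1
HLA-DMA
HLA-DMB
HLA-DOA
HLA-DOB
HLA-DPA1
HLA-DPB1
HLA-DQA1
HLA-DQA2
HLA-DQB1
HLA-DRA
HLA-DRB1
HLA-DRB3
HLA-DRB4
HLA-DRB5
TNF
IFNA1
IFNG
NLRC5
ERAP1
ERAP2
IRF1
FAS
MEX3B
JAK1
JAK2
STAT1
IFNGR1
IFNGR2
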