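symbol	category
SLA1A2	glia
VIM	glia
AQP4	glia
GFAP	astrocytes
S100B	astrocytes
SLC1A3	astrocytes
ALDH1L1	astrocytes
BYSL	astrocytes
GJA1	astrocytes
GLUL	astrocytes
PYGB	astrocytes
OLIG2	oligodendrocytes
CNP	oligodendrocytes
CA2	oligodendrocytes
NFIA	oligodendrocytes
NFIB	oligodendrocytes
PDGFRA	OPCs
SPP1	microglia
TMEM119	microglia
ITGAM	microglia
PTPRC	microglia
AIF1	microglia
RBFOX3	neurons
TBR1	neurons
SOX5	neurons
DCX	neurons
BCL11B	neurons
FEZF2	neurons
SATB2	neurons
CUX1	neurons
CUX2	neurons
POU3F2	neurons
POU3F3	neurons
TUBB3	neurons
NEUROD1	excitatory neurons
NEUROD2	excitatory neurons
NEUROD6	excitatory neurons
GRIN2B	excitatory neurons
CALB2	CGE
RELN	CGE
NR2F1	CGE
NR2F2	CGE
VIP	CGE
SIX3	LGE
ISL1	LGE
EBF1	LGE
LHX6	MGE
LHX8	MGE
MAF	MGE
SST	MGE
ERBB4	MGE
SOX6	MGE
NKX2-1	MGE
HES1	NPCs
HES5	NPCs
TYMS	NPCs
FABP7	NPCs
EOMES	NPCs
NEUROG1	NPCs
NCAM1	NPCs
TTYH1	NPCs
DLX2	NPCs
GAD2	NPCs
ASCL1	NPCs
NEUROG2	NPCs
PROX1	NPCs
TOP2A	NPCs
NUSAP1	NPCs
NR2E1	NPCs
CD24	NPCs
PAX6	NSCs
NES	NSCs
SOX1	NSCs
SOX2	NSCs
MCM2	NSCs
PCNA	NSCs
MKI67	NSCs
FOXO3	NSCs
BHLHE22	NSCs
REST	NSCs
HBB	RBC
HBM	RBC
HBA1	RBC
HBA2	RBC
IGFBP7	endothelial
PECAM1	endothelial
KRAT14	epithelial
KRAT16	epithelial
KRT17	epithelial
EMX2	epithelial
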