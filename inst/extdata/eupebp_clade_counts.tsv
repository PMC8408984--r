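# Curated counts of EuPEBP family members per gene clade in the major
# streptophyte lineages, compiled from the phylogenetics literature.
# Presence = count > 0; Charales absence reflects sparse sequence data.
taxon	prMFT	MFT	MFTA	MFTB	MFT1	MFT2	PFT	TCB	FTA	FTB	FT
Klebsormidiales	1	0	0	0	0	0	0	0	0	0	0
Charales	0	0	0	0	0	0	0	0	0	0	0
Coleochaetales	1	0	0	0	0	0	0	0	0	0	0
Zygnematales	4	0	0	0	0	0	0	0	0	0	0
Liverworts	0	2	0	0	0	0	0	0	0	0	0
Mosses	0	4	0	0	0	0	0	0	0	0	0
Hornworts	0	2	0	0	0	0	0	0	0	0	0
Lycophytes	0	14	0	0	0	0	0	0	0	0	0
Monilophytes	0	10	0	0	0	0	11	0	0	0	0
Gymnosperms	0	0	9	47	0	0	0	15	12	18	0
Angiosperms	0	0	0	0	56	12	0	165	0	0	324
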