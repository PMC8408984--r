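# Curated presence (1) / absence (0) of FT gene clades across monocot
# orders, compiled from the phylogenetics literature.
taxon	FTU	FTV	FT1	FT2	FT10	FTW	FTX	FTY	FTZ
Alismatales	1	1	0	0	0	0	0	0	0
Pandanales	0	0	1	1	1	0	1	1	0
Dioscoreales	0	0	0	1	1	0	0	1	0
Liliales	0	0	1	1	0	0	0	0	0
Asparagales	0	0	1	1	0	0	1	0	0
Zingiberales	0	0	1	1	1	0	1	1	0
Poales	0	0	1	1	1	1	1	1	1
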