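# Synthetic demonstration data generated by simulate_alignment(); clade and taxon labels are illustrative.
id	clade	taxon
EuFT_001	EuFT	Eudicots
EuFT_002	EuFT	Magnoliids
EuFT_003	EuFT	Eudicots
EuFT_004	EuFT	Magnoliids
EuFT_005	EuFT	Eudicots
EuFT_006	EuFT	Magnoliids
EuFT_007	EuFT	Eudicots
EuFT_008	EuFT	Magnoliids
FT1_001	FT1	Poales
FT1_002	FT1	Zingiberales
FT1_003	FT1	Poales
FT1_004	FT1	Zingiberales
FT1_005	FT1	Poales
FT1_006	FT1	Zingiberales
FT1_007	FT1	Poales
FT1_008	FT1	Zingiberales
FT10_001	FT10	Poales
FT10_002	FT10	Asparagales
FT10_003	FT10	Poales
FT10_004	FT10	Asparagales
FT10_005	FT10	Poales
FT10_006	FT10	Asparagales
FT10_007	FT10	Poales
FT10_008	FT10	Asparagales
AnTCB_001	AnTCB	Eudicots
AnTCB_002	AnTCB	Poales
AnTCB_003	AnTCB	Eudicots
AnTCB_004	AnTCB	Poales
AnTCB_005	AnTCB	Eudicots
AnTCB_006	AnTCB	Poales
AnTCB_007	AnTCB	Eudicots
AnTCB_008	AnTCB	Poales
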