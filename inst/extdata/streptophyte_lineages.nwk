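((((((((Angiosperms,Gymnosperms)seed_plants,Monilophytes)euphyllophytes,Lycophytes)vascular_plants,(Hornworts,(Mosses,Liverworts)setaphytes)bryophytes)land_plants,Zygnematales)zcc1,Coleochaetales)zcc2,Charales)zcc3,Klebsormidiales)streptophytes;
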