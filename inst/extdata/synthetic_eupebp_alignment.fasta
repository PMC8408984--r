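>EuFT_001
TFALEFTRHEFQYVRDKEFPFYCIDKKKKKKEVPFECADT
>EuFT_002
TFALEVTRHEFQYVRDKEFPFYCIDKKSKKKERPFECVDT
>EuFT_003
TFALLVTRCEFQYVRDNEFPFYCIDKKKKHKEVPFECVDT
>EuFT_004
TFACEVKRHEFQYVRDKEFPYYCIMKKKMKKEVFCECVDT
>EuFT_005
TEALEVTRHEAQYARVKMFDFYCIDLKKKKRHVPFVCVLT
>EuFT_006
WFWLEVTRHEFQYVRDKEFPFWCSDKKKKKKEVPFECVDE
>EuFT_007
TFALEVTRHCFVFVADKEFPFYCIDKQKKKKEVPFEGVDT
>EuFT_008
TFALEVTQHEFQYVRDKEHPFYMIDKKKKKKEVPFECVDT
>FT1_001
TFALEVTRHEFQYVRDKPFPFYCIDEEEEEREVPFECVDT
>FT1_002
TWALEVTTHEFFFVRDKEPPYYCIDEEWEERMVPFECVDT
>FT1_003
TFALEVTRHVFQYVRDKEFPFYCIDEEEEEREVPFECVDI
>FT1_004
AFALRVTRHEDQYVRDAEFPFYCIDEEEAKREVPFACVQT
>FT1_005
TFALEVTRPEFQYCDDKEFPFYCPDEEEEEREVPIECVDT
>FT1_006
TFPLEVTRHEFQYVRDKEFPFFPIVEEEEENEVPFECVDT
>FT1_007
TFAGETTRHEFQYVRFKEFSFYCIDEEEEEREVPFECVDT
>FT1_008
TFALEVERHEFQYVRDKEFPFYCIDFMEEEREWNFENYDT
>FT10_001
TFADEVTSHEFQYVRPKEWPFYCIDALMRIEPIDNNCVDT
>FT10_002
TFALEVIRHYCISVRDKEFPFDCHDALMRIEIRNFSSVHT
>FT10_003
TNALEVTRREFQYVRDKCFPFYCIDALMRIETMKYMCVDT
>FT10_004
RFALAVTRHEFQYVTDQEFPFYEIDALMRIECYHTYCVDT
>FT10_005
TFALEDTRHEFQYVRDKEFPPYCIMALMEIWFMCYKCVDT
>FT10_006
TFALEVTRHEFQYPRDKEFPFYCIDAGTRIEEVLGVCVDM
>FT10_007
TFALEVTRHEFQYVRDKEFWFYCIDALMRSEINGCHCQDT
>FT10_008
TFKLEVTRHEFQYVRDKEFPFYCIDRLMRIEHWYDPCVDT
>AnTCB_001
TFALEVTRHEFQYVRDKEFPFVCIFALMRIEEVPFP----
>AnTCB_002
DFALEVTEHEFQYVRRKEFPLYCTDALMRIMEVVHE-HR-
>AnTCB_003
TFALEVTRNEIQYVRDKEIPFYLIDALMAIEEVPFE----
>AnTCB_004
TNALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFEC--T
>AnTCB_005
TFALEVTRHEFQYVRDMEFPFYCIDQLMRIEEVPFECV--
>AnTCB_006
TFALFVTRHEFWYVRDKPFPFYCIDADIRIEEVPFEK---
>AnTCB_007
TFALEVWRHEFQYVEDKEFPFYCIDALMRTEEAPFE----
>AnTCB_008
TFDWELTRHGFQSARDKEFQFYCIDALMRIEVVPFE-V-T
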