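((Eudicots,Magnoliids)core_eudicot_side,((Zingiberales,Poales)commelinids,Asparagales)monocot_side)angiosperms;
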