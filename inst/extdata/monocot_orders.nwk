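(Alismatales,((Pandanales,Dioscoreales)pandanales_grade,(Liliales,(Asparagales,(Zingiberales,Poales)commelinids)n2)n1)non_alismatid_monocots)monocots;
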