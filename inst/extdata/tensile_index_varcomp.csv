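term,variance
Strip:Nanopaper,0.01
Section:Variety,57.40
Variety,6.74
HPH,110.59
Nanopaper,1.28
Residual,137.34
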