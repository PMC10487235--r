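factor,level,experimental,predicted,set
casamino,11,386.915,384,validation
gtp,0.03,403.18,402,validation
sodium_acetate,12,385.14,382,validation
glycine,12,380.69,383,validation
casamino,5,360.93,368,curve
gtp,0.02,391.495,398,curve
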