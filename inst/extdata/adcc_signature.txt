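TNFRSF9
TNF
BCL2
IL21R
BIRC3
IKZF2
CCR7
CD69
MKI67
CD226
CLEC2B
CXCR4
TIA1
TNFSF10
GZMA
TLR6
TLR1
CD244
CD38
TLR3
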