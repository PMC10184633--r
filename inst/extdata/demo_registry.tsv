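gene
GENE0001
GENE0002
GENE0003
GENE0004
GENE0005
GENE0006
GENE0007
GENE0008
GENE0009
GENE0010
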