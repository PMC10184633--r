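gene	keyword
GENE0001	extracellular
GENE0002	extracellular
GENE0003	extracellular
GENE0004	extracellular
GENE0005	extracellular
GENE0006	extracellular
GENE0007	GPI-anchor
GENE0008	GPI-anchor
GENE0009	secreted
GENE0010	secreted
GENE0011	secreted
GENE0012	secreted
GENE0013	secreted
GENE0014	secreted
GENE0015	signal
GENE0016	signal
GENE0017	signal
GENE0018	signal
GENE0019	extracellular region
GENE0020	extracellular region
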