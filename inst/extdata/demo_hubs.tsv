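gene	hub
GENE0001	NFKB_like
GENE0002	NFKB_like
GENE0003	NFKB_like
GENE0004	NFKB_like
GENE0005	NFKB_like
GENE0006	NFKB_like
GENE0007	NFKB_like
GENE0008	NFKB_like
GENE0009	JAK_STAT_like
GENE0010	JAK_STAT_like
GENE0011	JAK_STAT_like
GENE0012	JAK_STAT_like
GENE0013	JAK_STAT_like
GENE0014	JAK_STAT_like
GENE0015	JAK_STAT_like
GENE0016	JAK_STAT_like
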