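node_a	node_b	combined_score
GENE0010	GENE0028	0.802
GENE0019	GENE0017	0.475
GENE0028	GENE0027	0.529
GENE0007	GENE0014	0.472
GENE0002	GENE0004	0.207
GENE0015	GENE0025	0.92
GENE0026	GENE0003	0.344
GENE0022	GENE0013	0.771
GENE0008	GENE0021	0.652
GENE0003	GENE0009	0.627
GENE0024	GENE0021	0.48
GENE0008	GENE0022	0.851
GENE0022	GENE0008	0.347
GENE0015	GENE0013	0.513
GENE0008	GENE0015	0.584
GENE0027	GENE0009	0.593
GENE0026	GENE0002	0.506
GENE0019	GENE0021	0.708
GENE0020	GENE0008	0.472
GENE0008	GENE0026	0.955
GENE0018	GENE0024	0.234
GENE0015	GENE0010	0.805
GENE0006	GENE0014	0.361
GENE0016	GENE0026	0.741
GENE0022	GENE0008	0.513
GENE0021	GENE0016	0.246
GENE0004	GENE0018	0.782
GENE0011	GENE0023	0.694
GENE0006	GENE0005	0.697
GENE0026	GENE0006	0.647
GENE0023	GENE0003	0.824
GENE0002	GENE0021	0.345
GENE0004	GENE0009	0.858
GENE0006	GENE0016	0.619
GENE0024	GENE0030	0.574
GENE0011	GENE0023	0.645
GENE0002	GENE0001	0.97
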