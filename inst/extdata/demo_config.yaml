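# Demo pipeline configuration: simulate a four-layer stimulation time course,
# call differential events, classify combined responses, summarize temporal
# dynamics and network composition.
seed: 42
thresholds:
  alpha: 0.05
  alphaSecretome: 0.01
  lfcMin: 1.0
simulate:
  layers: [phospho, transcript, protein, secretome]
  n_per_class:
    TNF: 6
    IFN: 6
    COMMON: 6
    SYNERGY: 6
    "NULL": 6
  n_replicates: 3
  noise_sd: 0.2
impute: downshift
classify:
  baseline: ctrl_course
  rule: s4-or-e3
network:
  edges: demo_edges.tsv
  hubs: demo_hubs.tsv
  keywords: demo_keywords.tsv
  registry: demo_registry.tsv
  min_score: 0.95
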