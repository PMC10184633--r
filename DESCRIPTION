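Package: inflamap
Title: Multi-Omics Time-Course Dissection of Endothelial Cytokine Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting endothelial responses to TNF-alpha and
    IFN-gamma stimulation across phosphoproteome, transcriptome, proteome and
    secretome time courses. Implements empirical-Bayes moderated t-statistics
    with Benjamini-Hochberg control for per-timepoint differential-event
    calling, downshifted-normal imputation of intensity-dependent missing
    values, a shape/effect response-classification scheme based on Pearson
    correlations and trapezoidal AUC ratios (TNF-alpha, IFN-gamma, common,
    synergy), AUC-based synergy decomposition, cumulative temporal-event
    summaries with layer onset ordering, and interaction-network composition
    summaries. Includes a synthetic multi-omics time-course generator with
    known ground truth for validation, and a deterministic end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
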