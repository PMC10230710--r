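Package: qtlmed
Title: Causal Mediation Analysis for Molecular QTL Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring cell-type-specific causal gene-regulatory
    relationships from molecular quantitative trait locus (QTL) data.
    Implements fixed-effect cis/trans QTL scans with hierarchical
    multiple-testing correction, construction of variant-chromatin-gene and
    variant-gene-gene (X-M-Y) candidate triplets, Bayesian model selection
    over twelve causal DAG configurations with conjugate closed-form marginal
    likelihoods, an intraclass-correlation (ICC) measurement-error simulation
    that identifies and filters causal calls vulnerable to model flipping, a
    regression-based mediation comparator with a permutation null summarized
    by a generalized extreme value fit, Storey's pi1 replication statistics,
    and LD-threshold conditional colocalization with GWAS loci. A synthetic
    data generator with planted causal architectures provides a ground-truth
    test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
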