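Package: bloomshift
Title: Differential Expression, Population Shifts and Selection Signals in
    Bloom Metatranscriptomes
Version: 0.1.0
Authors@R: person("Monterey", "Bloomworks", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for nutrient-manipulated phytoplankton
    bloom metatranscriptomes. Implements trimmed-mean-of-M-values (TMM)
    normalization, conditional-likelihood negative-binomial dispersion
    estimation and the two-group NB exact test with Benjamini-Hochberg FDR;
    per-read percent-identity summaries and replicated percent-identity-shift
    detection against reference transcriptomes; pileup-based SNV calling with
    synonymous/nonsynonymous classification, per-taxon SNV density and
    allele-frequency sweep flags; Markov clustering of ORF similarity graphs
    with cluster-level differential-expression aggregation; and nutrient-status
    expression indices (NRT2:GSII for nitrogen, ISIP1-3:thiC for iron). A
    synthetic bloom-community generator with planted truth (expression
    effects, diverged subpopulations, SNV trajectories) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
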