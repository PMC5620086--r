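Package: startlenet
Title: Multi-Omics Association Mapping and Genetic Network Assembly for
    Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping of quantitative traits in fully inbred panels
    such as the Drosophila Genetic Reference Panel, using a mixed linear model
    with additive, epistatic and sex-interaction effects. Provides a two-step
    scan (single-locus pre-screen followed by permutation-calibrated
    experiment-wise thresholds), Gibbs-sampler effect estimation, variance
    component and heritability decomposition, four mapping layers
    (SNP-phenotype, transcript-phenotype, SNP-transcript,
    transcript-transcript), assembly of the layered
    genotype-transcript-phenotype network with export to GraphML, SIF and JSON,
    and a synthetic inbred-panel generator with known ground truth so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
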