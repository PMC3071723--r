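Package: twolibde
Title: Exact Two-Library Differential Expression Testing for Digital Gene
    Expression Counts
Version: 1.0.0
Authors@R:
    person("twolibde", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for sex-differential (or any two-condition) transcript
    analysis from per-contig read counts of two sequencing libraries without
    biological replicates. Implements the exact conditional (Audic-Claverie)
    enrichment test in log space, partition accounting of mixed and
    library-exclusive contigs, robust-candidate filtering by fold enrichment
    and read support, keyword-based candidate prediction from homology
    annotation tables, transcriptome coverage estimation from core eukaryotic
    gene (CEG) hits, and comparative-CT (delta-delta-CT) qRT-PCR relative
    quantification with two-group significance testing. A multinomial count
    simulator with known ground truth supports type-I-error and power
    evaluation of the test at realistic 454-scale library sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
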