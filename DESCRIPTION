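Package: fibrodiff
Title: Rank-Product Differential Expression and Differential Co-Expression
    Networks for Collagen-VI-Deficient Fibroblast Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for four-group (patient/control, with and
    without ascorbic-acid treatment) fibroblast expression studies: two-sample
    Rank Products differential expression with permutation-estimated
    proportion-of-false-positives (pfp), signed fold changes and
    probeset-to-gene collapsing; per-group Pearson co-expression networks with
    cross-group edge classification (patient-only, control-only, concordant,
    discordant); detection of genes whose fold change reverts sign under
    ascorbic-acid treatment; delta-delta-Ct relative quantification for
    qPCR/miRNA assays; phenotype-miRNA correlation screening; gene-set
    over-representation tests; and a synthetic-data generator with planted
    ground truth so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
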