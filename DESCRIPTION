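Package: bodymapr
Title: Multi-Tissue RNA-Seq Expression Atlas Analysis
Version: 0.1.0
Authors@R: person("BodyMap", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for gene x sample FPKM matrices from
    multi-tissue RNA-seq body maps: expression landscape summaries by gene
    biotype, hierarchical clustering with sample-outlier flagging, pairwise
    differential expression (Welch t-test with Benjamini-Hochberg FDR),
    tissue-specific and sex-dominated gene calling across fold-change grids,
    two-tier housekeeping/reference gene selection by expression stability,
    and ERCC spike-in linearity quality control. Includes a synthetic-data
    generator that plants ground-truth gene classes so every stage can be
    validated without external downloads, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
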