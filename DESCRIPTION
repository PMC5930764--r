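Package: ribostress
Title: Diet-Responsive rDNA Methylation and Sperm Small RNA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing genotype-dependent ribosomal DNA promoter
    methylation from targeted bisulfite amplicon sequencing (joint per-read
    calling of the A/C variant at -104 and CpG -133 methylation), sperm
    small RNA class composition and tRNA-derived fragment abundance, and
    the accompanying cohort statistics for litter-structured mouse designs
    (cluster-robust linear models, Fisher exact composition tests, Welch
    tests on litter means, one-way ANOVA). Includes synthetic-data
    generators that emulate a four-group pre-/post-weaning protein
    restriction study design so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    edgeR,
    optparse,
    knitr
Config/testthat/edition: 3
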