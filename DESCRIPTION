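Package: compexr
Title: Signal Dilution in RNA-Seq of Composite Anatomical Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how bulk RNA-seq of composite anatomical
    structures (for example a whole insect abdomen) dilutes and distorts
    differential-expression signal arising in small internal organs.
    Provides a generative tissue-mixture count simulator with an
    incomplete-homogenization model and known per-gene ground truth, RPKM
    quantification with transcriptome-membership calls and depth
    equalization, two differential-expression tests (an exact
    negative-binomial conditional test with Benjamini-Hochberg adjustment,
    and a nonparametric signal-versus-noise probability), and
    cross-extraction concordance analyses: false-negative and
    opposite-direction classification, presence/absence tables, dilution
    ratios, and Fisher's exact comparisons between focal tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
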