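Package: methdyn
Title: Targeted Dynamic-Methylome Panel Design and Tile-Based DMR Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing targeted bisulfite-sequencing capture
    panels from candidate differentially methylated regions (DMRs) and for
    analysing the resulting data. Implements candidate filtering and a
    three-component region score with balanced per-origin selection under a
    byte budget, eQTL-based augmentation and panel assembly; 200-bp tiling
    with coverage-weighted methylation aggregation, pairwise Fisher exact
    tests with Benjamini-Hochberg correction, DMR calling and merging;
    a Poisson multi-sample coverage-requirement model for cohort design;
    genomic feature-overlap annotation; and a seeded synthetic methylome
    generator with planted hypomethylated DMRs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
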