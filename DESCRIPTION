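Package: dupdiverge
Title: Structural, Expression and Selection Divergence of Duplicated Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for the evolution of large duplicated gene
    families (such as the nematode F-box family): tandem-duplication detection
    from gene order, duplication-loss parsimony reconciliation of gene trees
    against a species tree, a five-mechanism exon/intron structural-divergence
    classifier for closely related paralog pairs, dot-matrix tandem-repeat
    detection, Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction and
    sliding-window selection scans, and stage-specific expression divergence
    analysis. Includes simulators that generate every input with planted
    ground truth so the whole pipeline can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
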