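Package: mirtrans
Title: Correlating Transcriptional Activity with Mature miRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide correlation analysis between
    transcriptional activity around miRNA loci (RNA polymerase II ChIP-seq
    peak signal, or overlapping mRNA abundance) and mature miRNA expression.
    Pre-miRNA stem-loop coordinates are extended by configurable windows and
    overlapping signals aggregated per locus under strand-aware rules;
    miRNA sets are stratified by miRBase name-number cut-offs, experimental
    pri-miRNA evidence, and expression-based weighting; Spearman, Pearson and
    weighted Pearson correlations are computed with two-sided p-values,
    replicate-based attenuation (disattenuation) correction, Mann-Whitney
    group comparison, and hierarchical clustering of per-sample correlation
    profiles. A synthetic-data generator with known ground truth makes every
    stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
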