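Package: tsrkit
Title: Identification, Quantification and Target Analysis of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline toolkit for tRNA-derived small RNA (tsRNA) analysis.
    Calls bona fide tsRNAs from small RNA-seq reads using a binomial test of
    positional read enrichment on mature and precursor tRNA transcripts, with
    modification-aware alignment scoring; classifies fragments into the six
    canonical types (tRF-5, tRF-3, tRF-i, tRF-1, tiRNA-5, tiRNA-3), assigns
    stable names, and annotates whitelist membership. Quantifies expression as
    reads per million tRNA-mapped counts and normalizes cohorts with a
    rank-based inverse-Gaussian transform. Discovers tsRNA-mRNA interactions
    from CLIP tag pileups (local-maxima peak calling) and from CLASH/CLEAR
    chimeric reads (fake-chimera removal and arm splitting), pairing small RNA
    and target with a seed-anchored duplex search under a surrogate stacking
    energy and filtering binding sites by evolutionary conservation. Scores
    tsRNA-miRNA competing-endogenous-RNA pairs with a hypergeometric test of
    shared targets under Benjamini-Hochberg FDR control. Includes seeded
    generators for every input so the whole pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
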