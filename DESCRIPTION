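Package: intronevo
Title: Intron Loss and Gain Analysis on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of intron presence and absence
    in gene families across a phylogeny. Infers exon/intron structure from
    genomic and cDNA sequence pairs by splice-aware dynamic programming,
    projects intron positions of many orthologs onto a shared alignment to
    build a presence/absence matrix over ancestral intron slots, reconstructs
    minimum-event loss and gain histories on rooted trees (Dollo and Sankoff
    parsimony with explicit handling of undetermined states), quantifies
    splice-junction microhomology characteristic of non-homologous end
    joining, and discovers fixed-width intronic motifs with a
    one-occurrence-per-sequence EM model scored against an empirical
    resampling null. Ships a curated presence/absence matrix and composite
    species topology for the angiosperm ABCB1 auxin-transporter gene, and a
    full synthetic-data generator with ground-truth event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
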