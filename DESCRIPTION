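Package: exomescape
Title: Exome Landscapes of GC Content, Amino-Acid Usage and Protein Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes genome-wide "exome landscapes" for comparative
    vertebrate genomics: per-gene GC content of transcripts, amino-acid
    usage of encoded proteins grouped by codon base composition (GARP,
    FYMINK, mixed), and pairwise protein divergence from affine-gap global
    alignments, each smoothed by a 101-gene sliding window over a reference
    gene order. Landscapes from many species are compared by Pearson
    correlation and Euclidean distance and clustered into a dendrogram that
    can be checked against a reference phylogeny. A deterministic
    synthetic-genome simulator with regionally autocorrelated GC,
    GC-coupled amino-acid sampling, lineage-specific GC-biased gene
    conversion and synteny rearrangements provides a desk-scale test bed
    for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    yaml
Config/testthat/edition: 3
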