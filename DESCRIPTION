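Package: silentcode
Title: Ribosome Density Divergence Screen for Near-Identical Protein Isoform Families
Version: 0.1.0
Authors@R: person("silentcode", "maintainers", email = "silentcode@example.org",
    role = c("aut", "cre"))
Description: Identifies families of nearly identical protein isoforms encoded
    by different genes, quantifies each member's ribosome density from
    ribosome-profiling coverage tracks mapped onto spliced CDS coordinates,
    and ranks families by the normalized standard deviation (coefficient of
    variation) of member densities -- a screen for isoforms whose translation
    diverges despite near-identical protein sequence. Supporting tools cover
    codon-level silent-substitution analysis between homologous coding
    sequences, minimal-substitution CRISPR knock-in recoding design with
    restriction-digest genotyping diagnostics, and a fully synthetic data
    generator (genome, annotation, proteome, coverage tracks) for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
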