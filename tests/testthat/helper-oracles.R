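# Independent oracles and small fixture builders. Everything here must stay
# independent of the implementation paths it checks: the alignment oracle
# enumerates alignments recursively, the clustering oracle is igraph, the
# codon oracle is Biostrings translation.

# exhaustive enumeration over all global alignments of two tiny strings
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

oracle_components <- function(nodes, edges_a, edges_b) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_a, to = edges_b),
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  unname(lapply(split(nodes, comp$membership), sort))
}

oracle_translate <- function(nt) {
  # no.init.codon: plain codon semantics, no initiator TTG/CTG -> M mapping
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

random_nt_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# random sense codon (no stop)
random_codon <- function() {
  repeat {
    c3 <- random_nt_string(3)
    if (!c3 %in% c("TAA", "TAG", "TGA")) return(c3)
  }
}

# uniform coverage track over explicit intervals
toy_track <- function(df, track_id = "toy") {
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(df, path)
  read_bedgraph(path, track_id)
}

toy_tx <- function(starts, ends, strand = "+", chrom = "chr1",
                   gene = "G", tx = NULL) {
  if (is.null(tx)) tx <- paste0(gene, ".t1")
  transcript_model(tx, gene, chrom, strand, starts, ends,
                   protein_id = paste0(gene, ".p1"))
}

# enumerate every synonymous codon assignment for a target protein and return
# the minimum total Hamming distance to the source CDS
oracle_min_recode <- function(source_cds, target_protein) {
  tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(tab), unname(tab))
  codons <- substring(source_cds, seq(1, nchar(source_cds), 3),
                      seq(3, nchar(source_cds), 3))
  aa <- strsplit(target_protein, "")[[1]]
  choices <- lapply(aa, function(a) by_aa[[a]])
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  min(apply(grid, 1, function(row) {
    sum(mapply(ham, unname(unlist(row)), codons))
  }))
}
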