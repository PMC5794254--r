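# Published inputs for the mouse actin gene family: the composite ribosome
# density table, the knock-in donor template, the guide, and a reconstructed
# wild-type 5' CDS fragment. These are the package's worked example and the
# anchor for its acceptance tests.

.extdata <- function(...) {
  system.file("extdata", ..., package = "silentcode", mustWork = TRUE)
}

#' Composite ribosome densities of the mouse actin gene family
#'
#' The published characteristic densities (mean per-base coverage over the
#' first 150 codons, aggregated over 26 profiling studies) for the six mouse
#' actin genes, spanning ~3600-fold from Actg2 (0.377) to Actb (1351.607).
#'
#' @return Data frame: `name`, `gene_symbol`, `protein_acc`, `mrna_acc`,
#'   `composite_density`.
#' @examples
#' d <- actin_density_table()
#' normalized_sd(d$composite_density)   # ~2.31, far above the 1.4 threshold
#' @export
actin_density_table <- function() {
  read.delim(.extdata("actin_ribosome_densities.tsv"),
             stringsAsFactors = FALSE)
}

#' Published knock-in donor template for the beta-coded gamma-actin edit
#'
#' The homology-directed-repair donor that rewrites the first 10 codons of
#' mouse Actb to encode the gamma-actin N-terminus (MEEEIAALVI) via five point
#' mutations, destroying both the EcoRV site used for genotyping and the
#' guide/PAM match.
#'
#' @return A nucleotide [seq_record()] (151 nt, includes 5'UTR context).
#' @export
actb_donor_template <- function() {
  read_fasta(.extdata("actb_donor_template.fasta"), "nucleotide")[[1L]]
}

#' Coding region of the donor template
#'
#' The donor's in-frame coding portion (codons 1-30), starting at the ATG.
#'
#' @return A nucleotide [seq_record()] (90 nt).
#' @export
actb_donor_coding <- function() {
  donor <- actb_donor_template()
  at <- regexpr("ATGGAAGAGGAA", donor$residues, fixed = TRUE)
  seq_record("actb_donor_coding", substring(donor$residues, at),
             "donor template coding region, codons 1-30", "nucleotide")
}

#' Reconstructed wild-type Actb 5' CDS fragment (codons 1-30)
#'
#' NOT a downloaded reference sequence: reconstructed from the published
#' donor template by reverting the five knock-in point mutations, pinned by
#' the published guide protospacer (codons 6-10), the EcoRV site spanning
#' codons 4-5 and the canonical beta-actin N-terminal decapeptide MDDDIAALVV.
#' The two third-position codon choices not fixed by those constraints do not
#' affect any substitution count computed from this record.
#'
#' @return A nucleotide [seq_record()] (90 nt).
#' @export
actb_wt_5prime <- function() {
  read_fasta(.extdata("actb_wt_5prime_reconstructed.fasta"),
             "nucleotide")[[1L]]
}

#' Published CRISPR guide for the beta-coded gamma-actin edit
#'
#' @return List with `protospacer` (20 nt, matches the wild-type Actb coding
#'   strand over codons 6-10 plus two bases) and `pam` (`"CGG"`).
#' @export
actb_guide <- function() {
  list(protospacer = "GCTGCGCTGGTCGTCGACAA", pam = "CGG")
}
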