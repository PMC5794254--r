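# Codon-aligned comparison of two homologous CDSs: every codon pair is
# classified identical / silent-only (nucleotide change, same amino acid) /
# replacement (amino acid differs). This is the quantitative backbone of the
# silent-substitution analysis.

.codon_table <- function(code = "standard") {
  if (!identical(code, "standard")) {
    stop("only the standard genetic code is built in", call. = FALSE)
  }
  Biostrings::GENETIC_CODE
}

.split_codons <- function(nt) {
  substring(nt, seq.int(1L, nchar(nt), 3L), seq.int(3L, nchar(nt), 3L))
}

.translate_codons <- function(codons, tab) {
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"   # ambiguous bases
  aa
}

.as_cds_string <- function(x, what = "CDS") {
  if (inherits(x, "SequenceRecord")) {
    if (x$alphabet != "nucleotide") {
      stop(what, " must be nucleotide sequence", call. = FALSE)
    }
    x <- x$residues
  }
  x <- toupper(as.character(x))
  if (nchar(x) %% 3L != 0L) {
    stop(what, " length ", nchar(x), " is not divisible by 3", call. = FALSE)
  }
  x
}

.trim_stop <- function(codons, tab) {
  if (length(codons) && !is.na(tab[codons[length(codons)]]) &&
      tab[codons[length(codons)]] == "*") {
    codons <- codons[-length(codons)]
  }
  codons
}

#' Protein-guided codon alignment of two CDSs
#'
#' Both CDSs are translated (terminal stop codons trimmed first), the proteins
#' are globally aligned, and the alignment's gaps are mapped back onto codons.
#' Gapless columns yield codon pairs; gapped columns are excluded and counted.
#' An internal stop codon is an error naming its codon position.
#'
#' @param cds_a,cds_b Nucleotide [seq_record()] objects or strings; length
#'   divisible by 3 after stop trimming.
#' @param genetic_code Only `"standard"` is built in.
#' @return List of class `CodonAlignment`: `codons_a`, `codons_b` (equal-length
#'   character vectors of paired codons), `n_pairs`, `excluded_a`,
#'   `excluded_b` (codons falling in gap columns).
#' @export
codon_align <- function(cds_a, cds_b, genetic_code = "standard") {
  tab <- .codon_table(genetic_code)
  sa <- .as_cds_string(cds_a, "cds_a"); sb <- .as_cds_string(cds_b, "cds_b")
  ca <- .trim_stop(.split_codons(sa), tab)
  cb <- .trim_stop(.split_codons(sb), tab)
  for (side in list(list(ca, "cds_a"), list(cb, "cds_b"))) {
    aa <- .translate_codons(side[[1L]], tab)
    stops <- which(aa == "*")
    if (length(stops)) {
      stop("internal stop codon in ", side[[2L]], " at codon ", stops[1L],
           call. = FALSE)
    }
  }
  pa <- seq_record("a", paste(.translate_codons(ca, tab), collapse = ""),
                   alphabet = "protein")
  pb <- seq_record("b", paste(.translate_codons(cb, tab), collapse = ""),
                   alphabet = "protein")
  aln <- global_align(pa, pb)
  colsa <- strsplit(aln$aligned_a, "")[[1]]
  colsb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(colsa != "-")
  ib <- cumsum(colsb != "-")
  gapless <- colsa != "-" & colsb != "-"
  structure(
    list(codons_a = ca[ia[gapless]], codons_b = cb[ib[gapless]],
         n_pairs = sum(gapless),
         excluded_a = sum(colsa != "-" & colsb == "-"),
         excluded_b = sum(colsb != "-" & colsa == "-")),
    class = "CodonAlignment")
}

#' Pair codons positionally
#'
#' Builds a `CodonAlignment` from two equal-length codon vectors that are
#' already in register (e.g. equal-length CDSs known to be gaplessly
#' homologous), bypassing the protein-guided alignment of [codon_align()].
#'
#' @param codons_a,codons_b Equal-length character vectors of 3-mers.
#' @return A `CodonAlignment` with no exclusions.
#' @export
codon_pairs <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b),
            all(nchar(c(codons_a, codons_b)) == 3L))
  structure(list(codons_a = toupper(codons_a), codons_b = toupper(codons_b),
                 n_pairs = length(codons_a), excluded_a = 0L,
                 excluded_b = 0L),
            class = "CodonAlignment")
}

#' Classify substitutions between paired codons
#'
#' Each codon pair is classified as identical, silent-only (>= 1 nucleotide
#' difference, same amino acid) or replacement (amino acid differs; a codon
#' carrying both silent and replacement characters counts as replacement so
#' the classes partition). Pairs containing non-ACGT bases are excluded with a
#' warning.
#'
#' @param pairs A `CodonAlignment` from [codon_align()].
#' @param genetic_code Only `"standard"` is built in.
#' @return Object of class `SubstitutionReport`: `n_codons_compared`,
#'   `nt_differences`, `pct_nt_difference` (over `3 * n_codons_compared`
#'   bases), `codons_identical`, `codons_silent_only`, `codons_replacement`,
#'   `pct_codons_affected`, `pct_codons_silent_only`, `aa_differences`,
#'   `codons_excluded_ambiguous`, `codons_excluded_gaps`.
#' @export
classify_substitutions <- function(pairs, genetic_code = "standard") {
  stopifnot(inherits(pairs, "CodonAlignment"))
  tab <- .codon_table(genetic_code)
  ca <- pairs$codons_a; cb <- pairs$codons_b
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (any(!clean)) {
    warning(sum(!clean), " codon pair(s) with ambiguous bases excluded",
            call. = FALSE)
    ca <- ca[clean]; cb <- cb[clean]
  }
  n <- length(ca)
  ntdiff_per <- if (n) {
    mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
           ca, cb, USE.NAMES = FALSE)
  } else integer(0)
  aa_a <- .translate_codons(ca, tab); aa_b <- .translate_codons(cb, tab)
  repl <- aa_a != aa_b
  silent <- !repl & ntdiff_per > 0L
  ident <- !repl & ntdiff_per == 0L
  structure(
    list(n_codons_compared = n,
         nt_differences = sum(ntdiff_per),
         pct_nt_difference = if (n) 100 * sum(ntdiff_per) / (3 * n) else 0,
         codons_identical = sum(ident),
         codons_silent_only = sum(silent),
         codons_replacement = sum(repl),
         pct_codons_affected = if (n) 100 * (sum(silent) + sum(repl)) / n
                               else 0,
         pct_codons_silent_only = if (n) 100 * sum(silent) / n else 0,
         aa_differences = sum(repl),
         codons_excluded_ambiguous = sum(!clean),
         codons_excluded_gaps = pairs$excluded_a + pairs$excluded_b),
    class = "SubstitutionReport")
}

#' Codon-level divergence of two CDSs
#'
#' Convenience composition of [codon_align()] and [classify_substitutions()].
#'
#' @inheritParams codon_align
#' @return A `SubstitutionReport`.
#' @export
cds_divergence <- function(cds_a, cds_b, genetic_code = "standard") {
  classify_substitutions(codon_align(cds_a, cds_b, genetic_code), genetic_code)
}

#' @export
print.SubstitutionReport <- function(x, ...) {
  cat(sprintf(
    paste0("<SubstitutionReport: %d codons | %.2f%% nt difference | ",
           "%d identical / %d silent-only / %d replacement (%.1f%% ",
           "affected)>\n"),
    x$n_codons_compared, x$pct_nt_difference, x$codons_identical,
    x$codons_silent_only, x$codons_replacement, x$pct_codons_affected))
  invisible(x)
}
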