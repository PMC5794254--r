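# Knock-in recoding design: edit gene A's CDS to encode protein B with the
# fewest possible nucleotide substitutions, and the restriction-digest
# genotyping readout used to follow such edits.

#' Built-in restriction enzymes
#'
#' Exact-match recognition motifs with fixed cut offsets. EcoRV cuts bluntly
#' GAT^ATC (offset 3).
#' @return Named list of `list(motif, cut_offset)`.
#' @export
restriction_enzymes <- function() {
  list(EcoRV = list(motif = "GATATC", cut_offset = 3L))
}

.revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

.codons_for_aa <- function(tab) split(names(tab), unname(tab))

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Count base differences between two equal-length sequences
#'
#' @param seq_a,seq_b Nucleotide strings or [seq_record()]s of equal length
#'   (or equal-length windows).
#' @param window Optional `c(start, end)` 0-based half-open window applied to
#'   both sequences.
#' @return Integer count of mismatching positions.
#' @examples
#' count_substitutions("ACGT", "ACGA")   # 1
#' @export
count_substitutions <- function(seq_a, seq_b, window = NULL) {
  if (inherits(seq_a, "SequenceRecord")) seq_a <- seq_a$residues
  if (inherits(seq_b, "SequenceRecord")) seq_b <- seq_b$residues
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[2L] >= window[1L])
    seq_a <- substr(seq_a, window[1L] + 1L, window[2L])
    seq_b <- substr(seq_b, window[1L] + 1L, window[2L])
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences (or windows) differ in length: ", nchar(seq_a), " vs ",
         nchar(seq_b), call. = FALSE)
  }
  .hamming(seq_a, seq_b)
}

#' Minimal-substitution recoding of a CDS to a target protein
#'
#' For every codon whose amino acid must change, picks the synonymous codon of
#' the target residue at minimum Hamming distance from the source codon
#' (ties: lexicographically smallest codon); codons already encoding the
#' target residue are untouched. The result is the fewest-substitution edit of
#' the gene that swaps the encoded protein isoform.
#'
#' Constraints of the form `"disrupt:<motif>"` additionally require that the
#' edited CDS no longer matches `<motif>` (on either strand) anywhere it
#' matched in the source: where the minimal plan leaves a match intact, the
#' cheapest synonymous single-codon replacement overlapping the site is added.
#'
#' @param source_cds Nucleotide [seq_record()] or string, length divisible by
#'   3 (a terminal stop codon is trimmed); no internal stops.
#' @param target_protein Protein [seq_record()] or string, same codon count as
#'   the (trimmed) source.
#' @param constraints Character vector of constraints (see above).
#' @param genetic_code Only `"standard"` is built in.
#' @return Object of class `RecodePlan`: `substitutions` (data frame:
#'   `cds_position` 0-based, `ref_base`, `alt_base`, `codon_index` 1-based),
#'   `n_substitutions`, `edited_cds`, `constraints_applied`.
#' @export
minimal_recode <- function(source_cds, target_protein, constraints = character(0),
                           genetic_code = "standard") {
  tab <- .codon_table(genetic_code)
  src <- .as_cds_string(source_cds, "source_cds")
  codons <- .trim_stop(.split_codons(src), tab)
  src <- paste(codons, collapse = "")
  if (inherits(target_protein, "SequenceRecord")) {
    target_protein <- target_protein$residues
  }
  target <- toupper(as.character(target_protein))
  if (nchar(target) != length(codons)) {
    stop("target protein has ", nchar(target), " residues but source CDS has ",
         length(codons), " codons", call. = FALSE)
  }
  src_aa <- .translate_codons(codons, tab)
  if (any(src_aa == "*")) {
    stop("internal stop codon in source at codon ", which(src_aa == "*")[1L],
         call. = FALSE)
  }
  if (any(src_aa == "X")) {
    stop("untranslatable codon in source at codon ", which(src_aa == "X")[1L],
         call. = FALSE)
  }
  by_aa <- .codons_for_aa(tab)
  tgt_aa <- strsplit(target, "")[[1]]
  edited <- codons
  for (i in seq_along(codons)) {
    if (src_aa[i] == tgt_aa[i]) next
    cands <- by_aa[[tgt_aa[i]]]
    if (is.null(cands)) {
      stop("no codon encodes target residue '", tgt_aa[i], "' at position ",
           i, call. = FALSE)
    }
    d <- vapply(cands, .hamming, integer(1), b = codons[i])
    cands <- sort(cands[d == min(d)])
    edited[i] <- cands[1L]
  }

  applied <- character(0)
  for (con in constraints) {
    if (!grepl("^disrupt:", con)) {
      stop("unknown constraint: ", con, call. = FALSE)
    }
    motif <- toupper(sub("^disrupt:", "", con))
    edited <- .disrupt_motif(edited, codons, motif, tgt_aa, by_aa)
    applied <- c(applied, con)
  }

  edited_cds <- paste(edited, collapse = "")
  subs <- .diff_table(src, edited_cds)
  structure(
    list(substitutions = subs, n_substitutions = nrow(subs),
         edited_cds = edited_cds, constraints_applied = applied),
    class = "RecodePlan")
}

# positions where the minimal plan leaves the motif intact get the cheapest
# synonymous codon swap that breaks the match
.disrupt_motif <- function(edited, source, motif, tgt_aa, by_aa) {
  k <- nchar(motif)
  src_str <- paste(source, collapse = "")
  hit_pos <- c(.match_positions(src_str, motif),
               .match_positions(src_str, .revcomp(motif)))
  for (pos in sort(unique(hit_pos))) {
    window <- function(s) substr(paste(s, collapse = ""), pos + 1L, pos + k)
    broken <- function(s) {
      w <- window(s)
      w != motif && w != .revcomp(motif)
    }
    if (broken(edited)) next
    first_codon <- pos %/% 3L + 1L
    last_codon <- (pos + k - 1L) %/% 3L + 1L
    best <- NULL
    for (ci in seq.int(first_codon, min(last_codon, length(edited)))) {
      for (alt in sort(by_aa[[tgt_aa[ci]]])) {
        if (alt == edited[ci]) next
        trial <- edited
        trial[ci] <- alt
        if (!broken(trial)) next
        cost <- .hamming(alt, source[ci]) - .hamming(edited[ci], source[ci])
        key <- list(cost = cost, ci = ci, alt = alt)
        if (is.null(best) || cost < best$cost ||
            (cost == best$cost && (ci < best$ci ||
                                   (ci == best$ci && alt < best$alt)))) {
          best <- key
        }
      }
    }
    if (is.null(best)) {
      stop("constraint disrupt:", motif,
           " cannot be satisfied by synonymous edits", call. = FALSE)
    }
    edited[best$ci] <- best$alt
  }
  edited
}

.match_positions <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

.diff_table <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  at <- which(ca != cb)
  data.frame(cds_position = at - 1L, ref_base = ca[at], alt_base = cb[at],
             codon_index = (at - 1L) %/% 3L + 1L, stringsAsFactors = FALSE)
}

#' @export
print.RecodePlan <- function(x, ...) {
  cat(sprintf("<RecodePlan: %d substitution(s) over %d codon(s)%s>\n",
              x$n_substitutions, length(unique(x$substitutions$codon_index)),
              if (length(x$constraints_applied))
                paste0("; constraints: ",
                       paste(x$constraints_applied, collapse = ", "))
              else ""))
  if (nrow(x$substitutions)) print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Find restriction-site matches
#'
#' All 0-based start positions of exact motif matches. Palindromic motifs
#' (equal to their reverse complement, e.g. EcoRV GATATC) need one scan;
#' non-palindromic motifs are scanned on both strands with the strand
#' reported.
#'
#' @param seq Nucleotide string or [seq_record()].
#' @param motif Recognition motif over ACGT.
#' @return Data frame with columns `position` (0-based, on the given
#'   sequence) and `strand`.
#' @export
find_restriction_sites <- function(seq, motif) {
  if (inherits(seq, "SequenceRecord")) seq <- seq$residues
  seq <- toupper(seq); motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif must be over ACGT", call. = FALSE)
  }
  fwd <- .match_positions(seq, motif)
  rc <- .revcomp(motif)
  if (motif == rc) {
    return(data.frame(position = fwd,
                      strand = rep("+", length(fwd)),
                      stringsAsFactors = FALSE))
  }
  rev <- .match_positions(seq, rc)
  out <- data.frame(position = c(fwd, rev),
                    strand = c(rep("+", length(fwd)),
                               rep("-", length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Simulate a restriction digest of a linear amplicon
#'
#' Cuts at `position + cut_offset` for every plus-strand motif match and
#' returns the fragment lengths 5'->3'. Fragment lengths always sum to the
#' amplicon length; a linear molecule yields one more fragment than cuts.
#'
#' @param amplicon Nucleotide string or [seq_record()].
#' @param enzyme Name from [restriction_enzymes()] (default `"EcoRV"`), or
#'   supply `motif` + `cut_offset` directly.
#' @param motif,cut_offset Explicit recognition motif and cut offset
#'   (override `enzyme`).
#' @return Object of class `DigestResult`: `enzyme_name`,
#'   `recognition_motif`, `cut_positions` (0-based), `fragment_lengths`.
#' @examples
#' digest_fragments("AAGATATCAA")$fragment_lengths   # EcoRV: 5 and 5
#' @export
digest_fragments <- function(amplicon, enzyme = "EcoRV", motif = NULL,
                             cut_offset = NULL) {
  if (inherits(amplicon, "SequenceRecord")) amplicon <- amplicon$residues
  amplicon <- toupper(amplicon)
  if (is.null(motif)) {
    enz <- restriction_enzymes()[[enzyme]]
    if (is.null(enz)) stop("unknown enzyme: ", enzyme, call. = FALSE)
    motif <- enz$motif; cut_offset <- enz$cut_offset
  } else {
    if (is.null(cut_offset)) stop("cut_offset required with motif",
                                  call. = FALSE)
    enzyme <- "custom"
  }
  sites <- find_restriction_sites(amplicon, motif)
  cuts <- sort(unique(sites$position[sites$strand == "+"] + cut_offset))
  n <- nchar(amplicon)
  if (length(cuts) && (min(cuts) <= 0L || max(cuts) >= n)) {
    stop("cut position outside sequence", call. = FALSE)
  }
  bounds <- c(0L, cuts, n)
  structure(
    list(enzyme_name = enzyme, recognition_motif = motif,
         cut_positions = cuts, fragment_lengths = diff(bounds)),
    class = "DigestResult")
}

#' @export
print.DigestResult <- function(x, ...) {
  cat(sprintf("<DigestResult %s (%s): %d cut(s) -> fragments %s>\n",
              x$enzyme_name, x$recognition_motif, length(x$cut_positions),
              paste(x$fragment_lengths, collapse = " + ")))
  invisible(x)
}
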