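# Readers/writers for the formats the pipeline touches, plus the small S3
# containers the rest of the package computes on. All internal coordinates are
# 0-based half-open; conversion happens only at file boundaries (GFF3 is
# 1-based inclusive; bedGraph is already 0-based half-open).

.IUPAC_NT <- "ACGTURYSWKMBDHVN"
.IUPAC_AA <- "ACDEFGHIKLMNPQRSTVWYBXZJUO*"

.alphabet_chars <- function(alphabet) {
  switch(alphabet,
    nucleotide = strsplit(.IUPAC_NT, "")[[1]],
    protein = strsplit(.IUPAC_AA, "")[[1]],
    stop("unknown alphabet: ", alphabet, call. = FALSE)
  )
}

#' Create a sequence record
#'
#' A minimal FASTA-backed record: identifier, free-text description and the
#' residues themselves, stored uppercase. Characters are validated against the
#' IUPAC set of the declared alphabet (case-insensitive on input).
#'
#' @param id Record identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param residues Sequence string; stored uppercase.
#' @param description Remainder of the header line, may be `""`.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param allow_empty Permit a zero-length sequence (default `FALSE`).
#' @return An object of class `SequenceRecord`.
#' @examples
#' seq_record("a", "acgt")
#' @export
seq_record <- function(id, residues, description = "",
                       alphabet = c("nucleotide", "protein"),
                       allow_empty = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!allow_empty && !nzchar(residues)) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), .alphabet_chars(alphabet))
  if (length(bad)) {
    stop("sequence '", id, "' contains characters outside the ", alphabet,
         " IUPAC set: ", paste(bad, collapse = ""), call. = FALSE)
  }
  structure(
    list(id = id, description = description, residues = residues,
         alphabet = alphabet),
    class = "SequenceRecord"
  )
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("<SequenceRecord %s | %s | %d %s residues>\n", x$id,
              if (nzchar(x$description)) x$description else "-",
              nchar(x$residues), x$alphabet))
  invisible(x)
}

#' @export
nchar.SequenceRecord <- function(x, ...) nchar(x$residues)

.guess_alphabet <- function(residues) {
  chars <- unique(strsplit(toupper(paste(residues, collapse = "")), "")[[1]])
  if (length(chars) == 0L) return("nucleotide")
  if (all(chars %in% strsplit("ACGTUN", "")[[1]])) "nucleotide" else "protein"
}

#' Read a FASTA file
#'
#' Plain or gzip-compressed, wrapped or unwrapped. One `SequenceRecord` per
#' header, input order preserved, line wrapping removed. With
#' `alphabet = "auto"` the file is nucleotide iff every residue is in ACGTUN.
#'
#' @param path File path.
#' @param alphabet `"auto"`, `"nucleotide"` or `"protein"`.
#' @return List of [seq_record()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop(sprintf("%s:%d: expected FASTA header ('>'), got sequence data",
                 path, nonblank[1L]), call. = FALSE)
  }
  hdr_idx <- which(startsWith(lines, ">"))
  bad_hdr <- hdr_idx[!nzchar(trimws(substring(lines[hdr_idx], 2L)))]
  if (length(bad_hdr)) {
    stop(sprintf("%s:%d: malformed FASTA header (no identifier)",
                 path, bad_hdr[1L]), call. = FALSE)
  }
  bounds <- c(hdr_idx, length(lines) + 1L)
  records <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    header <- trimws(substring(lines[hdr_idx[k]], 2L))
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    body <- lines[seq.int(hdr_idx[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    residues <- gsub("\\s", "", paste(body, collapse = ""))
    ab <- if (alphabet == "auto") .guess_alphabet(residues) else alphabet
    rec <- tryCatch(
      seq_record(id, residues, desc, ab, allow_empty = TRUE),
      error = function(e) {
        stop(sprintf("%s:%d: %s", path, hdr_idx[k], conditionMessage(e)),
             call. = FALSE)
      }
    )
    records[[k]] <- rec
  }
  records
}

#' Write sequence records as FASTA
#'
#' @param records A `SequenceRecord` or list of them.
#' @param path Output file.
#' @param width Line-wrap width (0 = unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "SequenceRecord")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    hdr <- paste0(">", rec$id,
                  if (nzchar(rec$description)) paste0(" ", rec$description))
    body <- if (width > 0L && nchar(rec$residues) > 0L) {
      starts <- seq.int(1L, nchar(rec$residues), by = width)
      substring(rec$residues, starts, pmin(starts + width - 1L,
                                           nchar(rec$residues)))
    } else {
      rec$residues
    }
    out <- c(out, hdr, body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Create a transcript model
#'
#' A gene's CDS as an ordered list of genomic segments. Segments are stored
#' 0-based half-open and sorted 5'->3' in transcript orientation (ascending
#' genomic coordinates on `+`, descending on `-`). The model is the coordinate
#' backbone onto which coverage is mapped.
#'
#' @param transcript_id,gene_id,chromosome Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of 0-based half-open segment bounds
#'   (any order; they are sorted into transcript orientation).
#' @param gene_symbol,protein_id Optional annotations.
#' @return An object of class `TranscriptModel` with fields `cds_length`
#'   (spliced length) and `frame_ok` (length divisible by 3).
#' @export
transcript_model <- function(transcript_id, gene_id, chromosome, strand,
                             starts, ends, gene_symbol = "", protein_id = "") {
  stopifnot(strand %in% c("+", "-"), length(starts) == length(ends),
            length(starts) >= 1L)
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (any(ends <= starts)) stop("empty or inverted CDS segment", call. = FALSE)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts[-1L] < ends[-length(ends)])) {
    stop("overlapping CDS segments in transcript ", transcript_id,
         call. = FALSE)
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  len <- sum(ends - starts)
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_symbol = gene_symbol, chromosome = chromosome, strand = strand,
         cds_starts = starts, cds_ends = ends, protein_id = protein_id,
         cds_length = len, frame_ok = (len %% 3L == 0L)),
    class = "TranscriptModel"
  )
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("<TranscriptModel %s (%s) %s:%s %d segment(s), CDS %d nt%s>\n",
              x$transcript_id, x$gene_id, x$chromosome, x$strand,
              length(x$cds_starts), x$cds_length,
              if (x$frame_ok) "" else " [frame!]"))
  invisible(x)
}

#' Create a gene locus
#'
#' Groups the transcripts (and optionally protein sequences) annotated at one
#' gene.
#'
#' @param gene_id Gene identifier shared by all transcripts.
#' @param transcripts Non-empty list of [transcript_model()] objects.
#' @param proteins List of protein [seq_record()] objects (may be empty).
#' @return An object of class `GeneLocus`.
#' @export
gene_locus <- function(gene_id, transcripts, proteins = list()) {
  stopifnot(length(transcripts) >= 1L)
  ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  if (!all(ids == gene_id)) {
    stop("all transcripts in a locus must share gene_id ", gene_id,
         call. = FALSE)
  }
  structure(list(gene_id = gene_id, transcripts = transcripts,
                 proteins = proteins),
            class = "GeneLocus")
}

#' Read CDS features from a GFF3 file into gene loci
#'
#' CDS features are grouped by their `Parent` transcript, converted from GFF3's
#' 1-based inclusive coordinates to 0-based half-open, and ordered 5'->3' in
#' transcript orientation. Gene attribution is taken from a `gene_id` attribute
#' on the CDS line or, failing that, from the parent mRNA/transcript feature.
#'
#' @param path GFF3 file (plain or gzipped).
#' @return List of [gene_locus()] objects, sorted by gene_id.
#' @export
read_gff3_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  is_cds <- !is.na(meta$type) & meta$type == "CDS"
  if (!any(is_cds)) return(list())

  # transcript -> gene map from mRNA/transcript features, if present
  tx2gene <- character(0); tx2sym <- character(0)
  is_tx <- !is.na(meta$type) & meta$type %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    tid <- as.character(meta$ID[is_tx])
    par <- vapply(meta$Parent[is_tx], function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    gid <- if ("gene_id" %in% names(meta)) {
      as.character(meta$gene_id[is_tx])
    } else rep(NA_character_, sum(is_tx))
    gid[is.na(gid)] <- par[is.na(gid)]
    tx2gene <- setNames(gid, tid)
    if ("gene_name" %in% names(meta)) {
      tx2sym <- setNames(as.character(meta$gene_name[is_tx]), tid)
    }
  }

  cds <- gr[is_cds]
  cmeta <- S4Vectors::mcols(cds)
  parents <- vapply(seq_along(cds), function(i) {
    p <- cmeta$Parent[[i]]
    if (length(p) == 0L) {
      stop("CDS feature at ", as.character(GenomicRanges::seqnames(cds))[i],
           ":", GenomicRanges::start(cds)[i],
           " lacks a Parent transcript", call. = FALSE)
    }
    as.character(p[[1L]])
  }, character(1))

  get_attr <- function(col, i) {
    if (col %in% names(cmeta)) {
      v <- cmeta[[col]][i]
      if (is.list(v)) v <- if (length(v[[1L]])) v[[1L]][1L] else NA_character_
      v <- as.character(v)
      if (length(v) && !is.na(v)) return(v)
    }
    NA_character_
  }

  loci <- list()
  for (tx in unique(parents)) {
    sel <- which(parents == tx)
    strand <- unique(as.character(GenomicRanges::strand(cds))[sel])
    chrom <- unique(as.character(GenomicRanges::seqnames(cds))[sel])
    if (length(strand) != 1L || length(chrom) != 1L) {
      stop("transcript ", tx, " mixes chromosomes or strands", call. = FALSE)
    }
    if (!strand %in% c("+", "-")) {
      stop("transcript ", tx, " has no strand", call. = FALSE)
    }
    gid <- get_attr("gene_id", sel[1L])
    if (is.na(gid)) gid <- unname(tx2gene[tx])
    if (is.na(gid) || !length(gid)) gid <- tx
    sym <- get_attr("gene_name", sel[1L])
    if (is.na(sym)) sym <- if (tx %in% names(tx2sym)) unname(tx2sym[tx]) else ""
    pid <- get_attr("protein_id", sel[1L])
    if (is.na(pid)) pid <- ""
    tm <- transcript_model(
      transcript_id = tx, gene_id = gid, chromosome = chrom, strand = strand,
      starts = GenomicRanges::start(cds)[sel] - 1L,  # 1-based incl -> 0-based
      ends = GenomicRanges::end(cds)[sel],
      gene_symbol = if (is.na(sym)) "" else sym, protein_id = pid
    )
    loci[[gid]] <- c(loci[[gid]], list(tm))
  }
  out <- lapply(sort(names(loci)), function(g) gene_locus(g, loci[[g]]))
  out
}

#' Create a coverage track
#'
#' Per-chromosome, per-base non-negative read density. Internally stored as a
#' run-length encoded vector per chromosome; any base not covered by the input
#' has density 0.
#'
#' @param cov A named `RleList`-like list (one numeric Rle per chromosome), as
#'   produced by [GenomicRanges::coverage()].
#' @param track_id Track label.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, track_id = "track") {
  if (any(vapply(cov, function(r) min(S4Vectors::runValue(r), 0) < 0,
                 logical(1)))) {
    stop("coverage track contains negative densities", call. = FALSE)
  }
  structure(list(cov = cov, track_id = track_id), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("<CoverageTrack %s | %d chromosome(s)>\n", x$track_id,
              length(x$cov)))
  invisible(x)
}

#' Read a 4-column bedGraph file into a coverage track
#'
#' Every base of each interval receives the interval's value; unlisted bases
#' are 0. Overlapping intervals are rejected: densities must be pre-aggregated
#' (use [aggregate_tracks()] to combine studies).
#'
#' @param path bedGraph file (plain or gzipped), 0-based half-open.
#' @param track_id Track label (default: file basename).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, track_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(track_id)) track_id <- sub("\\.(bedgraph|bg)(\\.gz)?$", "",
                                         basename(path), ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) {
    return(coverage_track(GenomicRanges::coverage(gr), track_id))
  }
  if (any(gr$score < 0)) {
    stop("bedGraph ", path, " contains negative values", call. = FALSE)
  }
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits)) {
    i <- S4Vectors::queryHits(hits)[1L]
    stop("bedGraph ", path, " has overlapping intervals (e.g. near ",
         as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L,
         "); densities must be pre-aggregated", call. = FALSE)
  }
  cov <- GenomicRanges::coverage(gr, weight = as.numeric(gr$score))
  coverage_track(cov, track_id)
}

#' Per-base density over a genomic window
#'
#' @param track A [coverage_track()].
#' @param chromosome Chromosome name; unknown chromosomes yield all zeros.
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`.
#' @export
track_density <- function(track, chromosome, start, end) {
  stopifnot(inherits(track, "CoverageTrack"), end >= start)
  n <- end - start
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  if (!chromosome %in% names(track$cov)) return(out)
  r <- track$cov[[chromosome]]
  avail <- length(r)
  lo <- start + 1L                       # Rle is 1-based
  hi <- min(end, avail)
  if (hi >= lo) {
    out[seq_len(hi - lo + 1L)] <- as.numeric(S4Vectors::window(r, lo, hi))
  }
  out
}

#' Sum several coverage tracks base-wise
#'
#' Builds a composite track in the style of multi-study aggregated coverage.
#'
#' @param tracks Non-empty list of [coverage_track()] objects.
#' @param track_id Label for the composite.
#' @return A [coverage_track()].
#' @export
aggregate_tracks <- function(tracks, track_id = "composite") {
  stopifnot(length(tracks) >= 1L)
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$cov))))
  cov <- lapply(chroms, function(ch) {
    rles <- lapply(tracks, function(t) {
      if (ch %in% names(t$cov)) t$cov[[ch]] else NULL
    })
    rles <- rles[!vapply(rles, is.null, logical(1))]
    maxlen <- max(vapply(rles, length, integer(1)))
    acc <- S4Vectors::Rle(0, maxlen)
    for (r in rles) {
      if (length(r) < maxlen) r <- c(r, S4Vectors::Rle(0, maxlen - length(r)))
      acc <- acc + r
    }
    acc
  })
  names(cov) <- chroms
  coverage_track(cov, track_id)
}

#' Write intervals as a 4-column bedGraph
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), format(df$value, trim = TRUE,
                                              scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
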