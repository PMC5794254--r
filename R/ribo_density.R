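# Mapping coverage onto spliced CDS coordinates and the density statistic:
# the mean per-base coverage over the first 150 codons of the CDS.

#' Per-base coverage in spliced CDS coordinates
#'
#' Walks the transcript's CDS segments 5'->3' in transcript orientation and
#' concatenates the per-base densities, reversing each segment on the minus
#' strand. Position 1 of the result is the first base of the start codon;
#' exon junctions are seamless. A chromosome absent from the track yields an
#' all-zero vector.
#'
#' @param track A [coverage_track()].
#' @param tx A [transcript_model()].
#' @return Numeric vector of length `tx$cds_length`.
#' @export
spliced_cds_coverage <- function(track, tx) {
  stopifnot(inherits(tx, "TranscriptModel"))
  pieces <- lapply(seq_along(tx$cds_starts), function(k) {
    v <- track_density(track, tx$chromosome, tx$cds_starts[k], tx$cds_ends[k])
    if (tx$strand == "-") rev(v) else v
  })
  unlist(pieces, use.names = FALSE)
}

#' Characteristic ribosome density of a CDS
#'
#' Arithmetic mean of per-base density over the first `n_codons` codons
#' (default 150), i.e. the first `min(3 * n_codons, length)` bases; the window
#' simply truncates on shorter CDSs. The start codon is included; the stop
#' codon only if it falls inside the window.
#'
#' @param cds_vector Per-base density vector in CDS coordinates, e.g. from
#'   [spliced_cds_coverage()].
#' @param n_codons Window size in codons.
#' @return Non-negative mean density, with attribute `codons_used`.
#' @export
characteristic_density <- function(cds_vector, n_codons = 150L) {
  if (length(cds_vector) < 3L) {
    stop("CDS vector shorter than one codon", call. = FALSE)
  }
  n <- min(n_codons * 3L, length(cds_vector))
  structure(mean(cds_vector[seq_len(n)]), codons_used = n %/% 3L)
}

#' Composite ribosome density of a gene across tracks
#'
#' Aggregates several ribosome-profiling tracks into one characteristic
#' density. `sum_tracks` (default) sums coverage base-wise across tracks
#' before taking the density -- emulating a composite coverage track built
#' from many studies; `mean_tracks` averages the per-track characteristic
#' densities instead. With a single track the two agree.
#'
#' @param tracks Non-empty list of [coverage_track()] objects.
#' @param tx A [transcript_model()].
#' @param mode `"sum_tracks"` or `"mean_tracks"`.
#' @param n_codons Window size in codons (default 150).
#' @return An object of class `RiboDensity` with fields `gene_id`,
#'   `characteristic_density`, `codons_used`, `track_ids`,
#'   `aggregation_mode` and `frame_ok`.
#' @export
composite_density <- function(tracks, tx,
                              mode = c("sum_tracks", "mean_tracks"),
                              n_codons = 150L) {
  mode <- match.arg(mode)
  if (length(tracks) == 0L) stop("no coverage tracks supplied", call. = FALSE)
  vecs <- lapply(tracks, spliced_cds_coverage, tx = tx)
  dens <- if (mode == "sum_tracks") {
    characteristic_density(Reduce(`+`, vecs), n_codons)
  } else {
    per_track <- vapply(vecs, function(v)
      as.numeric(characteristic_density(v, n_codons)), numeric(1))
    structure(mean(per_track),
              codons_used = attr(characteristic_density(vecs[[1L]], n_codons),
                                 "codons_used"))
  }
  structure(
    list(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
         characteristic_density = as.numeric(dens),
         codons_used = attr(dens, "codons_used"),
         track_ids = vapply(tracks, function(t) t$track_id, character(1)),
         aggregation_mode = mode, frame_ok = tx$frame_ok),
    class = "RiboDensity"
  )
}

#' @export
print.RiboDensity <- function(x, ...) {
  cat(sprintf("<RiboDensity %s = %.4g over %d codons (%s, %d track(s))%s>\n",
              x$gene_id, x$characteristic_density, x$codons_used,
              x$aggregation_mode, length(x$track_ids),
              if (x$frame_ok) "" else " [frame!]"))
  invisible(x)
}

#' Characteristic densities for a set of loci
#'
#' Computes one density per gene, using the transcript that encodes the gene's
#' representative protein when `proteins` is supplied (matched by protein id),
#' otherwise the transcript with the longest CDS.
#'
#' @param loci List of [gene_locus()] objects.
#' @param tracks List of [coverage_track()] objects.
#' @param mode,n_codons See [composite_density()].
#' @param proteins Optional named list (gene_id -> protein record).
#' @return Data frame: gene_id, transcript_id, characteristic_density,
#'   codons_used, mode, frame_ok.
#' @export
density_table <- function(loci, tracks, mode = "sum_tracks", n_codons = 150L,
                          proteins = NULL) {
  rows <- lapply(loci, function(locus) {
    tx <- .pick_transcript(locus, proteins)
    d <- composite_density(tracks, tx, mode, n_codons)
    data.frame(gene_id = d$gene_id, transcript_id = d$transcript_id,
               characteristic_density = d$characteristic_density,
               codons_used = d$codons_used, mode = d$aggregation_mode,
               frame_ok = d$frame_ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.pick_transcript <- function(locus, proteins = NULL) {
  txs <- locus$transcripts
  if (!is.null(proteins) && locus$gene_id %in% names(proteins)) {
    want <- proteins[[locus$gene_id]]$id
    hit <- which(vapply(txs, function(t) identical(t$protein_id, want),
                        logical(1)))
    if (length(hit)) return(txs[[hit[1L]]])
  }
  lens <- vapply(txs, function(t) t$cds_length, integer(1))
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  txs[[order(-lens, ids)[1L]]]
}
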