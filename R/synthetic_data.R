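# Fully synthetic datasets: genome FASTA + GFF3 + proteome + CDS FASTA +
# bedGraph coverage tracks + a truth TSV, with planted isoform families of
# controlled protein identity and controlled density ratios. Everything every
# pipeline stage needs, with no downloads.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.STOPS <- c("TAA", "TAG", "TGA")

#' Specification of a synthetic dataset
#'
#' One spec + one seed is one dataset, byte-identical across runs. Member mean
#' densities within a family are geometrically spaced from `base_density` up
#' to `base_density * ratio` (the published actin family spans a roughly
#' log-uniform ladder across ~3600-fold, which this emulates). Per-base
#' coverage is drawn from a negative binomial around each gene's mean --
#' ribosome-profiling coverage is overdispersed -- with `nb_dispersion` as the
#' size parameter.
#'
#' @param seed Integer RNG seed.
#' @param n_families Number of planted families.
#' @param members_per_family Members per family (>= 2).
#' @param protein_length Residues per protein.
#' @param within_family_identity Percent identity of each mutated member to
#'   the family's ancestral protein, in \[85, 100\]. Member 1 IS the ancestor,
#'   so the planted pairwise identity of (member 1, member k) equals this
#'   value.
#' @param density_ratios Numeric vector, one max/min density ratio per family
#'   (recycled); default: log-spaced from 1 to 1000, the magnitude range seen
#'   across real isoform families.
#' @param density_means Optional list (one numeric vector per family) of
#'   explicit per-member mean densities, overriding
#'   `base_density`/`density_ratios`.
#' @param base_density Mean per-base density (per track) of a family's
#'   weakest member.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param n_exons_range Integer pair: min/max exons per gene.
#' @param strand_mix Fraction of genes placed on the minus strand.
#' @param n_tracks Number of coverage tracks to emit.
#' @return Validated spec object (class `SyntheticDatasetSpec`).
#' @export
synthetic_spec <- function(seed = 1L, n_families = 6L,
                           members_per_family = 3L, protein_length = 120L,
                           within_family_identity = 95,
                           density_ratios = NULL, density_means = NULL,
                           base_density = 2, nb_dispersion = 0.5,
                           n_exons_range = c(2L, 5L), strand_mix = 0.5,
                           n_tracks = 3L) {
  if (is.null(density_ratios)) {
    density_ratios <- 10^seq(0, 3, length.out = max(n_families, 2L))
  }
  spec <- list(seed = as.integer(seed), n_families = as.integer(n_families),
               members_per_family = as.integer(members_per_family),
               protein_length = as.integer(protein_length),
               within_family_identity = within_family_identity,
               density_ratios = rep_len(density_ratios, n_families),
               density_means = density_means,
               base_density = base_density, nb_dispersion = nb_dispersion,
               n_exons_range = as.integer(n_exons_range),
               strand_mix = strand_mix, n_tracks = as.integer(n_tracks))
  stopifnot(spec$n_families >= 1L, spec$members_per_family >= 2L,
            spec$protein_length >= 10L,
            spec$within_family_identity >= 85,
            spec$within_family_identity <= 100,
            all(spec$density_ratios > 0), spec$base_density > 0,
            spec$nb_dispersion > 0,
            length(spec$n_exons_range) == 2L, spec$n_exons_range[1L] >= 1L,
            spec$n_exons_range[2L] >= spec$n_exons_range[1L],
            spec$strand_mix >= 0, spec$strand_mix <= 1, spec$n_tracks >= 1L)
  n_mut <- round((1 - spec$within_family_identity / 100) * spec$protein_length)
  if (n_mut > spec$protein_length) {
    stop("infeasible identity/length combination", call. = FALSE)
  }
  if (!is.null(density_means)) {
    stopifnot(is.list(density_means),
              length(density_means) == spec$n_families)
    stopifnot(all(vapply(density_means, function(m) {
      length(m) == spec$members_per_family && all(m > 0)
    }, logical(1))))
  }
  structure(spec, class = "SyntheticDatasetSpec")
}

.mutate_protein <- function(aa, n_mut) {
  if (n_mut == 0L) return(aa)
  at <- sample(length(aa), n_mut)
  for (i in at) aa[i] <- sample(setdiff(.AA20, aa[i]), 1L)
  aa
}

.reverse_translate <- function(aa, by_aa) {
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run-length merge of per-base values into bedGraph intervals
.runs_to_bedgraph <- function(chrom, start0, values) {
  r <- rle(values)
  ends <- start0 + cumsum(r$lengths)
  starts <- c(start0, ends[-length(ends)])
  keep <- r$values > 0
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], value = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Each family starts from a random ancestral protein; member 1 is the
#' ancestor, the rest are point-mutated to the requested identity. Every
#' member is reverse-translated with synonymous codons chosen uniformly at
#' random (planting silent divergence between members), given a stop codon,
#' split into exons and embedded in a synthetic chromosome on a random strand.
#' Coverage tracks draw per-base negative-binomial counts around each gene's
#' assigned mean density over its CDS bases. A truth TSV records everything
#' planted.
#'
#' @param spec A [synthetic_spec()].
#' @param outdir Output directory (created if needed).
#' @return List of file paths (`genome`, `gff3`, `proteins`, `cds`, `tracks`,
#'   `truth`) plus the spec, invisibly classed `SyntheticDataset`.
#' @export
generate_dataset <- function(spec, outdir) {
  stopifnot(inherits(spec, "SyntheticDatasetSpec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  by_aa <- .codons_for_aa(.codon_table())
  by_aa <- lapply(by_aa, sort)
  n_mut <- round((1 - spec$within_family_identity / 100) * spec$protein_length)

  genome <- character(0)
  gff <- c("##gff-version 3")
  prot_recs <- list(); cds_recs <- list()
  truth <- list()
  gene_density <- list()   # per gene: chrom, genomic CDS positions, mean

  for (f in seq_len(spec$n_families)) {
    fam_id <- sprintf("FAM%03d", f)
    chrom <- sprintf("chr%d", f)
    anc <- sample(.AA20, spec$protein_length, replace = TRUE)
    ratio <- spec$density_ratios[f]
    means <- if (!is.null(spec$density_means)) {
      spec$density_means[[f]]
    } else if (spec$members_per_family == 1L) {
      spec$base_density
    } else {
      spec$base_density *
        ratio^((seq_len(spec$members_per_family) - 1) /
                 (spec$members_per_family - 1))
    }
    chrom_seq <- .random_nt(300L)
    chrom_feats <- character(0)

    for (m in seq_len(spec$members_per_family)) {
      gid <- sprintf("%s_G%d", fam_id, m)
      tid <- paste0(gid, ".t1")
      pid <- paste0(gid, ".p1")
      aa <- if (m == 1L) anc else .mutate_protein(anc, n_mut)
      cds <- paste0(.reverse_translate(aa, by_aa),
                    .STOPS[sample.int(3L, 1L)])
      strand <- if (runif(1) < spec$strand_mix) "-" else "+"
      n_ex <- sample(seq.int(spec$n_exons_range[1L], spec$n_exons_range[2L]),
                     1L)
      n_ex <- min(n_ex, nchar(cds))
      # split the spliced CDS into n_ex contiguous chunks
      cuts <- if (n_ex > 1L) {
        sort(sample(seq_len(nchar(cds) - 1L), n_ex - 1L))
      } else integer(0)
      bounds <- c(0L, cuts, nchar(cds))
      chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
      # genomic order: reverse chunk order and revcomp each on minus strand
      gchunks <- if (strand == "-") {
        vapply(rev(chunks), .revcomp, character(1))
      } else chunks
      introns <- if (n_ex > 1L) sample(50:200, n_ex - 1L, replace = TRUE)
                 else integer(0)
      seg_starts <- integer(n_ex); seg_ends <- integer(n_ex)
      pos <- nchar(chrom_seq)
      for (k in seq_len(n_ex)) {
        seg_starts[k] <- pos
        chrom_seq <- paste0(chrom_seq, gchunks[k])
        pos <- pos + nchar(gchunks[k])
        seg_ends[k] <- pos
        if (k < n_ex) {
          chrom_seq <- paste0(chrom_seq, .random_nt(introns[k]))
          pos <- pos + introns[k]
        }
      }
      chrom_seq <- paste0(chrom_seq, .random_nt(200L))

      # transcript-orientation phase for each genomic segment
      tx_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      phase <- integer(n_ex)
      done <- 0L
      for (k in tx_order) {
        phase[k] <- (3L - done %% 3L) %% 3L
        done <- done + (seg_ends[k] - seg_starts[k])
      }
      attrs <- function(id, parent = NULL, extra = "") {
        paste0("ID=", id,
               if (!is.null(parent)) paste0(";Parent=", parent) else "",
               extra)
      }
      gene_lo <- min(seg_starts) + 1L; gene_hi <- max(seg_ends)
      chrom_feats <- c(
        chrom_feats,
        sprintf("%s\tsilentcode\tgene\t%d\t%d\t.\t%s\t.\t%s", chrom, gene_lo,
                gene_hi, strand,
                attrs(gid, extra = paste0(";gene_id=", gid, ";gene_name=",
                                          gid))),
        sprintf("%s\tsilentcode\tmRNA\t%d\t%d\t.\t%s\t.\t%s", chrom, gene_lo,
                gene_hi, strand,
                attrs(tid, gid, paste0(";gene_id=", gid))),
        sprintf("%s\tsilentcode\tCDS\t%d\t%d\t.\t%s\t%d\t%s", chrom,
                seg_starts + 1L, seg_ends, strand, phase,
                attrs(paste0(tid, ".cds"), tid,
                      paste0(";gene_id=", gid, ";protein_id=", pid)))
      )
      prot_recs[[pid]] <- seq_record(pid, paste(aa, collapse = ""),
                                     paste0("gene_id=", gid), "protein")
      cds_recs[[tid]] <- seq_record(tid, cds, paste0("gene_id=", gid),
                                    "nucleotide")
      cds_pos <- unlist(lapply(seq_len(n_ex), function(k)
        seq.int(seg_starts[k], seg_ends[k] - 1L)))
      gene_density[[gid]] <- list(chrom = chrom, pos = cds_pos,
                                  mean = means[m])
      truth[[gid]] <- data.frame(
        family_id = fam_id, gene_id = gid, protein_id = pid,
        member_index = m,
        identity_to_ancestor = if (m == 1L) 100 else
          100 * (1 - n_mut / spec$protein_length),
        mean_density = means[m], family_ratio = max(means) / min(means),
        strand = strand, n_exons = n_ex, cds_length = nchar(cds),
        stringsAsFactors = FALSE)
    }
    genome[chrom] <- chrom_seq
    gff <- c(gff, chrom_feats)
  }

  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    gff3 = file.path(outdir, "annotation.gff3"),
    proteins = file.path(outdir, "proteins.fasta"),
    cds = file.path(outdir, "cds.fasta"),
    tracks = file.path(outdir, sprintf("track_%02d.bedgraph",
                                       seq_len(spec$n_tracks))),
    truth = file.path(outdir, "truth.tsv"))

  write_fasta(mapply(function(id, s) seq_record(id, s, alphabet = "nucleotide"),
                     names(genome), genome, SIMPLIFY = FALSE),
              paths$genome)
  writeLines(gff, paths$gff3)
  write_fasta(prot_recs, paths$proteins)
  write_fasta(cds_recs, paths$cds)

  for (t in seq_len(spec$n_tracks)) {
    rows <- lapply(names(gene_density), function(gid) {
      g <- gene_density[[gid]]
      counts <- rnbinom(length(g$pos), mu = g$mean, size = spec$nb_dispersion)
      # split at intron gaps: runs only merge within contiguous blocks
      block <- cumsum(c(1L, diff(g$pos) != 1L))
      do.call(rbind, lapply(split(seq_along(g$pos), block), function(idx) {
        .runs_to_bedgraph(g$chrom, g$pos[idx[1L]], counts[idx])
      }))
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    write_bedgraph(df, paths$tracks[t])
  }

  truth_df <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(structure(c(paths, list(spec = spec, truth_table = truth_df)),
                      class = "SyntheticDataset"))
}

#' Plant a six-member family shaped like the actin gene family
#'
#' Six near-identical members whose mean densities are proportional to the
#' published composite ribosome densities of the six mouse actin genes
#' (0.377 ... 1351.607, a ~3600-fold ladder), scaled by `scale`. The fixture
#' is emitted as a complete dataset bundle and, run through [run_screen()],
#' passes the minimum-density filter and exceeds the divergence threshold at
#' `scale = 1`; rescaled so the best member drops below 1 it is discarded.
#'
#' @param seed RNG seed.
#' @param outdir Output directory.
#' @param scale Multiplier applied to all six density means.
#' @param equal_means Replace the ladder with six equal means (a null family).
#' @param ... Further arguments to [synthetic_spec()].
#' @return See [generate_dataset()].
#' @export
plant_actin_like_family <- function(seed, outdir, scale = 1,
                                    equal_means = FALSE, ...) {
  dens <- sort(actin_density_table()$composite_density) * scale
  if (equal_means) dens <- rep(mean(dens), 6L)
  spec <- synthetic_spec(
    seed = seed, n_families = 1L, members_per_family = 6L,
    protein_length = 375L, within_family_identity = 99,
    density_means = list(dens), n_tracks = 1L, ...)
  generate_dataset(spec, outdir)
}
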