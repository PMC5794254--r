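# The headline screen: score isoform families by divergence of member
# ribosome densities, drop families whose best-translated member is below the
# density floor, rank by normalized SD and select the top of the list.

#' Normalized standard deviation (coefficient of variation)
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. This is
#' the family divergence statistic: 0 when all members translate equally, and
#' for a two-member family it approaches its maximum sqrt(2) as one member's
#' density dominates. `scale = "log"` instead returns the SD of log10
#' densities over strictly positive values (a geometric-dispersion
#' alternative; CV of logs is ill-defined when the mean log is <= 0).
#'
#' @param densities Numeric vector of >= 2 non-negative values, not all zero.
#' @param scale `"raw"` (default, the CV) or `"log"`.
#' @return Non-negative real.
#' @examples
#' normalized_sd(c(5, 5, 5))      # 0
#' normalized_sd(c(7, 0))         # sqrt(2)
#' @export
normalized_sd <- function(densities, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  densities <- as.numeric(densities)
  if (length(densities) < 2L) {
    stop("normalized SD needs at least 2 densities", call. = FALSE)
  }
  if (any(densities < 0)) stop("densities must be non-negative", call. = FALSE)
  if (scale == "log") {
    pos <- densities[densities > 0]
    if (length(pos) < 2L) return(NA_real_)
    return(sd(log10(pos)))
  }
  m <- mean(densities)
  if (m == 0) {
    stop("mean density is zero (all-silent family)", call. = FALSE)
  }
  sd(densities) / m
}

#' Score isoform families with member densities
#'
#' Attaches each member's characteristic density to its family and computes
#' the divergence statistics. Members without a density leave the family
#' `incomplete`: it is still scored on the available members (if >= 2) but is
#' excluded from selection by default.
#'
#' @param families List from [cluster_families()].
#' @param densities Named numeric vector or data frame from [density_table()]
#'   (gene_id -> characteristic density).
#' @return List of `FamilyScore` objects with fields `family_id`, `densities`
#'   (named), `max_density`, `normalized_sd`, `log_sd`, `incomplete`,
#'   `passed_min_density` (NA until [apply_filters()]), `selected`, `rank`.
#' @export
score_families <- function(families, densities) {
  if (is.data.frame(densities)) {
    densities <- setNames(densities$characteristic_density, densities$gene_id)
  }
  lapply(families, function(f) {
    have <- f$member_gene_ids %in% names(densities)
    d <- densities[f$member_gene_ids[have]]
    nsd <- if (length(d) >= 2L && any(d > 0)) normalized_sd(d) else NA_real_
    lsd <- if (length(d) >= 2L) normalized_sd(d, scale = "log") else NA_real_
    structure(
      list(family_id = f$family_id,
           member_gene_ids = f$member_gene_ids,
           densities = d,
           max_density = if (length(d)) max(d) else NA_real_,
           normalized_sd = nsd,
           log_sd = lsd,
           incomplete = !all(have),
           passed_min_density = NA,
           selected = FALSE,
           rank = NA_integer_),
      class = "FamilyScore")
  })
}

#' Minimum-density filter
#'
#' Discards (flags) families whose best-translated member has characteristic
#' density below the floor: such families are negligibly represented in the
#' polysome fraction. The boundary is inclusive (max density exactly at the
#' floor passes).
#'
#' @param scores List of `FamilyScore` objects from [score_families()].
#' @param min_max_density Density floor (default 1.0).
#' @return The scores with `passed_min_density` set.
#' @export
apply_filters <- function(scores, min_max_density = 1.0) {
  lapply(scores, function(s) {
    s$passed_min_density <- !is.na(s$max_density) &&
      s$max_density >= min_max_density
    s
  })
}

#' Rank families by divergence and select the top of the list
#'
#' Families passing the minimum-density filter (and complete, unless
#' `include_incomplete`) are sorted by normalized SD descending, ties broken
#' by family id for reproducibility. A family is selected iff its normalized
#' SD meets `sd_threshold` and its rank is within `top_n`.
#'
#' @param scores Output of [apply_filters()].
#' @param sd_threshold Normalized-SD selection threshold (default 1.4).
#' @param top_n Maximum number of selected families (default 100).
#' @param include_incomplete Allow incomplete families into the ranking.
#' @return The full score list, ranked families first (with `rank` and
#'   `selected` set), then filtered-out families.
#' @export
rank_and_select <- function(scores, sd_threshold = 1.4, top_n = 100L,
                            include_incomplete = FALSE) {
  if (!length(scores)) return(list())
  eligible <- vapply(scores, function(s) {
    isTRUE(s$passed_min_density) && !is.na(s$normalized_sd) &&
      (include_incomplete || !s$incomplete)
  }, logical(1))
  surv <- scores[eligible]
  rest <- scores[!eligible]
  if (length(surv)) {
    o <- order(-vapply(surv, function(s) s$normalized_sd, numeric(1)),
               vapply(surv, function(s) s$family_id, character(1)))
    surv <- surv[o]
    for (i in seq_along(surv)) {
      surv[[i]]$rank <- i
      surv[[i]]$selected <- surv[[i]]$normalized_sd >= sd_threshold &&
        i <= top_n
    }
  }
  c(surv, rest)
}

#' Screen configuration
#'
#' Defaults are the screen's published operating point: 90% identity over 90%
#' of length for family membership, density floor 1.0 on the best member,
#' normalized-SD threshold 1.4, top 100 families, 150-codon density window,
#' base-wise summation of tracks.
#'
#' @param identity_threshold,length_threshold Family-membership gates.
#' @param strict Strict (`>`) instead of inclusive (`>=`) threshold
#'   comparisons.
#' @param min_max_density Density floor for the best-translated member.
#' @param sd_threshold,top_n Selection rule.
#' @param n_codons Density window in codons.
#' @param mode Track aggregation, see [composite_density()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @param exclude_frame_flagged Drop genes whose CDS length is not a multiple
#'   of 3 before scoring.
#' @return Named list of settings.
#' @export
screen_config <- function(identity_threshold = 90, length_threshold = 0.9,
                          strict = FALSE, min_max_density = 1.0,
                          sd_threshold = 1.4, top_n = 100L, n_codons = 150L,
                          mode = "sum_tracks",
                          denominator = "longer_sequence",
                          exclude_frame_flagged = FALSE) {
  list(identity_threshold = identity_threshold,
       length_threshold = length_threshold, strict = strict,
       min_max_density = min_max_density, sd_threshold = sd_threshold,
       top_n = as.integer(top_n), n_codons = as.integer(n_codons),
       mode = mode, denominator = denominator,
       exclude_frame_flagged = exclude_frame_flagged)
}

#' Run the full silent-code screen
#'
#' End-to-end composition: representative (longest) protein per locus ->
#' similarity edges -> single-linkage families -> per-gene characteristic
#' densities from the coverage tracks -> family scoring, filtering, ranking
#' and selection. Genes present in the proteome but absent from the
#' annotation are logged and leave their families flagged incomplete.
#'
#' @param proteins Protein FASTA path, list of [seq_record()] objects, or a
#'   named list (gene_id -> record). FASTA records are matched to loci by
#'   protein id (or a `gene_id=` tag in the description).
#' @param annotation GFF3 path or list of [gene_locus()] objects.
#' @param tracks Character vector of bedGraph paths or list of
#'   [coverage_track()] objects.
#' @param config From [screen_config()].
#' @return List of class `ScreenResult`: `report` (one data frame row per
#'   scored family, ranked first), `scores`, `families`, `densities`,
#'   `manifest`.
#' @export
run_screen <- function(proteins, annotation, tracks,
                       config = screen_config()) {
  loci <- if (is.character(annotation)) read_gff3_cds(annotation)
          else annotation
  if (is.character(proteins)) proteins <- read_fasta(proteins, "protein")
  if (is.character(tracks)) tracks <- lapply(tracks, read_bedgraph)
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)

  if (!is.null(names(proteins)) && all(nzchar(names(proteins)))) {
    by_gene <- proteins
    loci <- .attach_proteins(loci, by_gene)
  } else {
    loci <- .attach_proteins(loci, .proteins_by_gene(loci, proteins))
  }
  reps <- suppressWarnings(longest_protein_per_locus(loci))

  if (isTRUE(config$exclude_frame_flagged)) {
    ok <- vapply(loci, function(l) {
      any(vapply(l$transcripts, function(t) t$frame_ok, logical(1)))
    }, logical(1))
    loci <- loci[ok]
    reps <- reps[names(reps) %in%
                   vapply(loci, function(l) l$gene_id, character(1))]
  }

  edges <- similarity_edges(reps, config$identity_threshold,
                            config$length_threshold, config$strict,
                            config$denominator)
  families <- cluster_families(edges, reps)

  annotated <- vapply(loci, function(l) l$gene_id, character(1))
  missing <- setdiff(unlist(lapply(families, function(f) f$member_gene_ids)),
                     annotated)
  if (length(missing)) {
    message("WARN: ", length(missing),
            " family gene(s) absent from annotation: ",
            paste(missing, collapse = ", "))
  }

  dens <- density_table(loci[match(sort(annotated), annotated)], tracks,
                        mode = config$mode, n_codons = config$n_codons,
                        proteins = reps)
  scores <- score_families(families, dens)
  scores <- apply_filters(scores, config$min_max_density)
  scores <- rank_and_select(scores, config$sd_threshold, config$top_n)

  structure(
    list(report = screen_report(scores), scores = scores,
         families = families, densities = dens,
         manifest = run_manifest(thresholds = config)),
    class = "ScreenResult")
}

#' Tabulate family scores
#'
#' @param scores List of `FamilyScore` objects (any stage).
#' @return Data frame: family_id, n_members, members, densities
#'   (comma-joined, member order), max_density, normalized_sd, log_sd,
#'   passed_min_density, incomplete, rank, selected.
#' @export
screen_report <- function(scores) {
  if (!length(scores)) {
    return(data.frame(family_id = character(0), n_members = integer(0),
                      members = character(0), densities = character(0),
                      max_density = numeric(0), normalized_sd = numeric(0),
                      log_sd = numeric(0), passed_min_density = logical(0),
                      incomplete = logical(0), rank = integer(0),
                      selected = logical(0)))
  }
  df <- do.call(rbind, lapply(unname(scores), function(s) {
    data.frame(
      family_id = s$family_id,
      n_members = length(s$member_gene_ids),
      members = paste(s$member_gene_ids, collapse = ","),
      densities = paste(format(unname(s$densities), trim = TRUE,
                               digits = 10), collapse = ","),
      max_density = s$max_density,
      normalized_sd = s$normalized_sd,
      log_sd = s$log_sd,
      passed_min_density = isTRUE(s$passed_min_density),
      incomplete = s$incomplete,
      rank = s$rank,
      selected = s$selected,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(df) <- NULL
  df
}

#' @export
print.ScreenResult <- function(x, ...) {
  sel <- sum(x$report$selected)
  cat(sprintf("<ScreenResult: %d families scored, %d selected>\n",
              nrow(x$report), sel))
  if (nrow(x$report)) {
    print(utils::head(x$report[, c("family_id", "max_density",
                                   "normalized_sd", "rank", "selected")], 10))
  }
  invisible(x)
}

# match loose protein records to loci: by protein_id recorded in the
# annotation, else by a "gene_id=<g>" tag in the FASTA description
.proteins_by_gene <- function(loci, records) {
  pid2gene <- character(0)
  for (l in loci) {
    for (t in l$transcripts) {
      if (nzchar(t$protein_id)) pid2gene[t$protein_id] <- l$gene_id
    }
  }
  out <- list()
  for (rec in records) {
    g <- NA_character_
    if (rec$id %in% names(pid2gene)) {
      g <- pid2gene[[rec$id]]
    } else if (grepl("gene_id=", rec$description)) {
      g <- sub(".*gene_id=(\\S+).*", "\\1", rec$description)
    }
    if (is.na(g)) {
      message("WARN: protein ", rec$id, " matches no annotated gene")
      next
    }
    out[[g]] <- c(out[[g]], list(rec))
  }
  out
}

.attach_proteins <- function(loci, by_gene) {
  lapply(loci, function(l) {
    p <- by_gene[[l$gene_id]]
    if (is.null(p)) p <- list()
    if (inherits(p, "SequenceRecord")) p <- list(p)
    gene_locus(l$gene_id, l$transcripts, p)
  })
}
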