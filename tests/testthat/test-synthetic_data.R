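test_that("spec validation enforces stated ranges", {
  expect_error(synthetic_spec(within_family_identity = 80), "identity")
  expect_error(synthetic_spec(members_per_family = 1), "members_per_family")
  expect_error(synthetic_spec(base_density = 0), "base_density")
  expect_s3_class(synthetic_spec(), "SyntheticDatasetSpec")
})

test_that("identical spec + seed gives byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  spec <- synthetic_spec(seed = 7, n_families = 2)
  ds1 <- generate_dataset(spec, d1)
  ds2 <- generate_dataset(spec, d2)
  files <- function(ds) unlist(ds[c("genome", "gff3", "proteins", "cds",
                                    "tracks", "truth")])
  sums1 <- unname(tools::md5sum(files(ds1)))
  sums2 <- unname(tools::md5sum(files(ds2)))
  expect_equal(sums1, sums2)
  # and a different seed changes the content
  ds3 <- generate_dataset(synthetic_spec(seed = 8, n_families = 2),
                          tempfile())
  expect_false(all(unname(tools::md5sum(files(ds3))) == sums1))
})

test_that("planted protein identity is recovered by the alignment module", {
  ds <- generate_dataset(synthetic_spec(seed = 12, n_families = 2,
                                        members_per_family = 3,
                                        protein_length = 100,
                                        within_family_identity = 98),
                         tempfile())
  prots <- read_fasta(ds$proteins, "protein")
  byid <- setNames(prots, vapply(prots, function(p) p$id, ""))
  tr <- ds$truth_table
  for (fam in unique(tr$family_id)) {
    rows <- tr[tr$family_id == fam, ]
    anc <- byid[[rows$protein_id[rows$member_index == 1]]]
    for (m in 2:3) {
      mem <- byid[[rows$protein_id[rows$member_index == m]]]
      pid <- as.numeric(percent_identity(global_align(anc, mem)))
      # within +-1 residue of the requested identity
      expect_lte(abs(pid - 98), 100 / 100)
    }
  }
})

test_that("generated files parse cleanly through the readers, no warnings", {
  ds <- generate_dataset(synthetic_spec(seed = 5, n_families = 2), tempfile())
  expect_no_warning({
    genome <- read_fasta(ds$genome, "nucleotide")
    prots <- read_fasta(ds$proteins, "protein")
    cds <- read_fasta(ds$cds, "nucleotide")
    loci <- read_gff3_cds(ds$gff3)
    tracks <- lapply(ds$tracks, read_bedgraph)
  })
  expect_length(loci, 6)
  expect_length(prots, 6)
  # every CDS length divisible by 3 and frame flags set
  for (l in loci) {
    expect_true(all(vapply(l$transcripts, function(t) t$frame_ok, TRUE)))
  }
})

test_that("annotated CDS matches the emitted CDS FASTA through the genome", {
  ds <- generate_dataset(synthetic_spec(seed = 31, n_families = 2,
                                        strand_mix = 0.5), tempfile())
  genome <- read_fasta(ds$genome, "nucleotide")
  chrom_seq <- setNames(lapply(genome, function(g) g$residues),
                        vapply(genome, function(g) g$id, ""))
  cds <- read_fasta(ds$cds, "nucleotide")
  cds_by_tx <- setNames(lapply(cds, function(c) c$residues),
                        vapply(cds, function(c) c$id, ""))
  loci <- read_gff3_cds(ds$gff3)
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  for (l in loci) {
    tx <- l$transcripts[[1]]
    spliced <- paste(vapply(seq_along(tx$cds_starts), function(k) {
      piece <- substr(chrom_seq[[tx$chromosome]], tx$cds_starts[k] + 1L,
                      tx$cds_ends[k])
      if (tx$strand == "-") rc(piece) else piece
    }, character(1)), collapse = "")
    expect_equal(spliced, cds_by_tx[[tx$transcript_id]],
                 info = tx$transcript_id)
  }
})

test_that("recovered densities converge to planted means with track count", {
  mean_err <- function(n_tracks, seed) {
    ds <- generate_dataset(synthetic_spec(
      seed = seed, n_families = 2, members_per_family = 2,
      density_ratios = c(10, 10), n_tracks = n_tracks), tempfile())
    loci <- read_gff3_cds(ds$gff3)
    tracks <- lapply(ds$tracks, read_bedgraph)
    dens <- density_table(loci, tracks, mode = "mean_tracks")
    tr <- ds$truth_table
    mean(abs(dens$characteristic_density[match(tr$gene_id, dens$gene_id)] -
               tr$mean_density) / tr$mean_density)
  }
  e1 <- mean(vapply(1:3, function(s) mean_err(1, 200 + s), 1))
  e26 <- mean(vapply(1:3, function(s) mean_err(26, 300 + s), 1))
  expect_lt(e26, e1)
  expect_lt(e26, 0.1)
})

test_that("planted density ratio is recovered within 20%", {
  ds <- generate_dataset(synthetic_spec(seed = 55, n_families = 1,
                                        members_per_family = 2,
                                        density_ratios = 1000,
                                        base_density = 1), tempfile())
  loci <- read_gff3_cds(ds$gff3)
  tracks <- lapply(ds$tracks, read_bedgraph)
  dens <- density_table(loci, tracks)
  d <- setNames(dens$characteristic_density, dens$gene_id)
  ratio <- max(d) / min(d)
  expect_lt(abs(ratio - 1000) / 1000, 0.2)
})

test_that("actin-like fixture behaves like the published family", {
  ds <- plant_actin_like_family(seed = 9, outdir = tempfile())
  res <- run_screen(ds$proteins, ds$gff3, ds$tracks)
  rep <- res$report
  expect_equal(nrow(rep), 1)
  expect_true(rep$passed_min_density)
  expect_gte(rep$normalized_sd, 1.4)
  expect_equal(rep$normalized_sd, 2.30715, tolerance = 0.05)
  expect_true(rep$selected)

  # rescaled so the best member is below 1 -> discarded
  dim <- plant_actin_like_family(seed = 9, outdir = tempfile(),
                                 scale = 0.0005)
  res2 <- run_screen(dim$proteins, dim$gff3, dim$tracks)
  expect_false(res2$report$passed_min_density)
  expect_false(res2$report$selected)

  # all-equal means -> normalized SD ~ 0
  flat <- plant_actin_like_family(seed = 9, outdir = tempfile(),
                                  equal_means = TRUE)
  res3 <- run_screen(flat$proteins, flat$gff3, flat$tracks)
  # bound = twice the per-member NB sampling noise of the 450-base window
  # (sd/mean ~ sqrt((mu + mu^2/size)/450)/mu ~ 0.07 at mu ~ 237, size 0.5)
  expect_lt(res3$report$normalized_sd, 0.15)
})
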