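test_that("read_fasta handles single, empty and wrapped records", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$residues, "ACGT")

  writeLines(character(0), f)
  expect_length(read_fasta(f), 0)

  set.seed(11)
  full <- random_nt_string(180)
  writeLines(c(">wrapped desc here", substring(full, c(1, 61, 121),
                                               c(60, 120, 180))), f)
  rec <- read_fasta(f)[[1]]
  expect_equal(nchar(rec$residues), 180)
  expect_equal(rec$residues, full)   # oracle: naive line concatenation
  expect_equal(rec$description, "desc here")
})

test_that("read_fasta errors name the offending line", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a"), f)
  expect_error(read_fasta(f), ":1:")
  writeLines(c(">a", "ACGT", ">", "CCGG"), f)
  expect_error(read_fasta(f), ":3:")
  writeLines(c(">a", "AC!T"), f)
  expect_error(read_fasta(f, "nucleotide"), ":1:.*characters")
})

test_that("FASTA round-trip preserves id, description and residues", {
  set.seed(7)
  recs <- lapply(1:5, function(i) {
    seq_record(paste0("s", i), random_aa_string(sample(10:200, 1)),
               description = c("", "free text desc")[i %% 2 + 1],
               alphabet = "protein")
  })
  f <- tempfile(fileext = ".faa")
  write_fasta(recs, f, width = 37)
  back <- read_fasta(f, "protein")
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$description, recs[[i]]$description)
    expect_equal(back[[i]]$residues, recs[[i]]$residues)
  }
  # independent parser agrees on the residues
  bs <- Biostrings::readBStringSet(f)
  expect_equal(unname(as.character(bs)),
               vapply(recs, function(r) r$residues, character(1)))
})

test_that("sequences are stored uppercase and validated per alphabet", {
  expect_equal(seq_record("x", "acgt")$residues, "ACGT")
  expect_error(seq_record("x", "MEEE"), "characters outside")
  expect_silent(seq_record("x", "MEEE", alphabet = "protein"))
  expect_error(seq_record("x", ""), "empty")
})

test_that("GFF3 CDS parsing converts coordinates and orders by strand", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA;gene_id=gA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=tA;Parent=gA;gene_id=gA",
    "chr1\tsrc\tCDS\t100\t149\t.\t+\t0\tID=cA;Parent=tA;gene_id=gA",
    "chr2\tsrc\tgene\t150\t400\t.\t-\t.\tID=gB;gene_id=gB",
    "chr2\tsrc\tmRNA\t150\t400\t.\t-\t.\tID=tB;Parent=gB;gene_id=gB",
    "chr2\tsrc\tCDS\t201\t260\t.\t-\t0\tID=cB;Parent=tB;gene_id=gB",
    "chr2\tsrc\tCDS\t301\t345\t.\t-\t0\tID=cB;Parent=tB;gene_id=gB"), gff)
  loci <- read_gff3_cds(gff)
  expect_length(loci, 2)
  txA <- loci[[1]]$transcripts[[1]]
  expect_equal(txA$cds_starts, 99L)      # 1-based inclusive -> 0-based
  expect_equal(txA$cds_ends, 149L)
  expect_equal(txA$cds_length, 50L)
  txB <- loci[[2]]$transcripts[[1]]
  # minus strand: transcript order is reverse genomic (oracle: manual flip)
  expect_equal(txB$cds_starts, c(300L, 200L))
  expect_equal(txB$cds_ends, c(345L, 260L))
  expect_equal(txB$cds_length, 45L + 60L)
  expect_true(txB$frame_ok)    # 105 nt is divisible by 3
})

test_that("GFF3 conversion preserves inclusive-interval lengths", {
  # for every feature, (half-open end - start) = (incl end - incl start + 1)
  gff <- tempfile(fileext = ".gff3")
  set.seed(3)
  starts1 <- sort(sample(1000, 5)) * 10
  lens <- sample(30:90, 5)
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ts\tCDS\t%d\t%d\t.\t+\t0\tID=c;Parent=t1;gene_id=g1",
            starts1, starts1 + lens - 1L)), gff)
  tx <- read_gff3_cds(gff)[[1]]$transcripts[[1]]
  expect_equal(tx$cds_ends - tx$cds_starts, lens)
})

test_that("GFF3 CDS without Parent or with overlap is rejected", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ts\tCDS\t1\t30\t.\t+\t0\tID=c1"), gff)
  expect_error(read_gff3_cds(gff), "Parent")
  writeLines(c("##gff-version 3",
               "chr1\ts\tCDS\t1\t30\t.\t+\t0\tID=c;Parent=t;gene_id=g",
               "chr1\ts\tCDS\t20\t50\t.\t+\t0\tID=c;Parent=t;gene_id=g"), gff)
  expect_error(read_gff3_cds(gff), "overlap")
})

test_that("bedGraph expansion, zero default and overlap rejection", {
  tr <- toy_track(data.frame(chrom = "chr1", start = 10, end = 13,
                             value = 2.5))
  expect_equal(track_density(tr, "chr1", 10, 14), c(2.5, 2.5, 2.5, 0))
  expect_equal(track_density(tr, "chr2", 0, 5), rep(0, 5))

  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t1.0", "chr1\t3\t8\t1.0"), f)
  expect_error(read_bedgraph(f), "overlap")
  writeLines("chr1\t0\t5\t-1", f)
  expect_error(read_bedgraph(f), "negative")
})

test_that("bedGraph total mass equals sum of value x width", {
  set.seed(5)
  starts <- cumsum(sample(5:30, 20))
  widths <- sample(1:10, 20, replace = TRUE)
  vals <- round(runif(20, 0, 50), 2)
  df <- data.frame(chrom = "chrZ", start = starts, end = starts + widths,
                   value = vals)
  tr <- toy_track(df)
  mass <- sum(track_density(tr, "chrZ", 0, max(df$end) + 10))
  expect_equal(mass, sum(vals * widths))
})

test_that("readers accept gzip-compressed input", {
  f <- tempfile(fileext = ".fasta.gz")
  con <- gzfile(f, "wt")
  writeLines(c(">z desc", "ACGTACGT"), con)
  close(con)
  rec <- read_fasta(f)[[1]]
  expect_equal(rec$residues, "ACGTACGT")
})
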