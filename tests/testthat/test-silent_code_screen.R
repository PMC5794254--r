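mk_score <- function(id, dens) {
  structure(list(family_id = id, member_gene_ids = names(dens),
                 densities = dens, max_density = max(dens),
                 normalized_sd = normalized_sd(dens),
                 log_sd = NA_real_, incomplete = FALSE,
                 passed_min_density = NA, selected = FALSE,
                 rank = NA_integer_),
            class = "FamilyScore")
}

test_that("normalized_sd: closed forms and error contract", {
  expect_equal(normalized_sd(c(5, 5, 5)), 0)
  for (d in c(0.1, 1, 7, 1000)) {
    expect_equal(normalized_sd(c(d, 0)), sqrt(2))
  }
  expect_error(normalized_sd(5), "at least 2")
  expect_error(normalized_sd(c(0, 0)), "all-silent")
  expect_error(normalized_sd(c(-1, 2)), "non-negative")
})

test_that("two-member normalized_sd increases with ratio toward sqrt(2)", {
  ratios <- c(1, 2, 5, 10, 100, 1e4, 1e8)
  vals <- vapply(ratios, function(r) normalized_sd(c(r, 1)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(max(vals), sqrt(2))
  expect_equal(vals[length(vals)], sqrt(2), tolerance = 1e-4)
})

test_that("normalized_sd is scale invariant", {
  set.seed(14)
  for (i in 1:20) {
    d <- runif(sample(2:8, 1), 0, 100)
    c0 <- runif(1, 0.01, 1000)
    expect_equal(normalized_sd(d * c0), normalized_sd(d))
  }
})

test_that("minimum-density filter: boundaries from the discard rule", {
  scores <- list(mk_score("lo", c(a = 0.9, b = 0.2)),
                 mk_score("edge", c(a = 1.0, b = 0.001)),
                 mk_score("actin", c(a = 1351.607, b = 1.289)))
  out <- apply_filters(scores)
  expect_false(out[[1]]$passed_min_density)   # below 1 -> discarded
  expect_true(out[[2]]$passed_min_density)    # inclusive boundary
  expect_true(out[[3]]$passed_min_density)
})

test_that("ranking sorts by SD desc, applies threshold and top_n", {
  mk3 <- function(ids, sds) {
    lapply(seq_along(ids), function(i) {
      s <- mk_score(ids[i], c(a = 1, b = 1))
      s$normalized_sd <- sds[i]
      s$max_density <- 10
      s$passed_min_density <- TRUE
      s
    })
  }
  out <- rank_and_select(mk3(c("f1", "f2", "f3"), c(1.1, 2.3, 1.5)))
  expect_equal(vapply(out, function(s) s$family_id, ""),
               c("f2", "f3", "f1"))
  expect_equal(vapply(out, function(s) s$selected, TRUE),
               c(TRUE, TRUE, FALSE))
  # 150 families all above threshold -> exactly 100 selected
  many <- mk3(sprintf("g%03d", 1:150), seq(1.4, 3, length.out = 150))
  out2 <- rank_and_select(many)
  expect_equal(sum(vapply(out2, function(s) s$selected, TRUE)), 100)
  # ties broken by family id
  tied <- rank_and_select(mk3(c("zz", "aa"), c(2, 2)))
  expect_equal(vapply(tied, function(s) s$family_id, ""), c("aa", "zz"))
  expect_length(rank_and_select(list()), 0)
})

test_that("screen ranking is invariant under global density scaling", {
  set.seed(15)
  fams <- lapply(1:6, function(i) {
    structure(list(family_id = paste0("F", i),
                   member_gene_ids = paste0("F", i, c("a", "b", "c")),
                   member_protein_ids = paste0("p", i, 1:3),
                   pairwise_identity_summary = c(min = 95, mean = 95,
                                                 max = 95)),
              class = "IsoformFamily")
  })
  dens <- setNames(runif(18, 0.5, 200),
                   unlist(lapply(fams, function(f) f$member_gene_ids)))
  run <- function(d) {
    out <- rank_and_select(apply_filters(score_families(fams, d),
                                         min_max_density = 0))
    list(ids = vapply(out, function(s) s$family_id, ""),
         nsd = vapply(out, function(s) s$normalized_sd, 1))
  }
  r1 <- run(dens)
  r2 <- run(dens * 37.5)
  expect_equal(r1$ids, r2$ids)
  expect_equal(r1$nsd, r2$nsd)
})

test_that("incomplete families are scored but excluded from selection", {
  fam <- structure(list(family_id = "F", member_gene_ids = c("a", "b", "c"),
                        member_protein_ids = c("pa", "pb", "pc"),
                        pairwise_identity_summary = c(min = 95, mean = 95,
                                                      max = 95)),
                   class = "IsoformFamily")
  scores <- score_families(list(fam), c(a = 100, b = 0))  # c missing
  expect_true(scores[[1]]$incomplete)
  expect_false(is.na(scores[[1]]$normalized_sd))
  out <- rank_and_select(apply_filters(scores))
  expect_false(out[[1]]$selected)
  out2 <- rank_and_select(apply_filters(scores), include_incomplete = TRUE)
  expect_true(out2[[1]]$selected)
})

test_that("run_screen recovers planted structure on synthetic data", {
  dir <- tempfile()
  # one extreme family (ratio 1000), one flat family
  spec <- synthetic_spec(seed = 101, n_families = 2, members_per_family = 2,
                         density_ratios = c(1000, 1))
  ds <- generate_dataset(spec, dir)
  res <- run_screen(ds$proteins, ds$gff3, ds$tracks)
  rep <- res$report
  expect_equal(nrow(rep), 2)
  top <- rep[rep$rank == 1, ]
  expect_equal(top$family_id, "FAM001_G1+FAM001_G2")
  expect_equal(top$normalized_sd, sqrt(2), tolerance = 0.02)
  expect_true(top$selected)
  flat <- rep[rep$family_id == "FAM002_G1+FAM002_G2", ]
  expect_lt(flat$normalized_sd, 0.2)
  expect_false(flat$selected)
})

test_that("run_screen discards a planted family whose best member is dim", {
  dir <- tempfile()
  spec <- synthetic_spec(seed = 102, n_families = 1, members_per_family = 2,
                         density_means = list(c(0.05, 0.5)), n_tracks = 1)
  ds <- generate_dataset(spec, dir)
  res <- run_screen(ds$proteins, ds$gff3, ds$tracks)
  expect_false(res$report$passed_min_density[1])
  expect_false(res$report$selected[1])
})
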