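test_that("column identity equals the fraction of identical usable pairs", {
  expect_equal(column_identity_score(c("A", "A", "A", "A")), 1.0)
  expect_equal(column_identity_score(c("A", "A", "A", "C")), 0.5)
  expect_true(is.na(column_identity_score(c("A", "-", "-", "X"))))
  expect_true(is.na(column_identity_score("A")))
  # exhaustive pair enumeration agrees on random columns with gaps and 'X'
  set.seed(11)
  pool <- c(aa_states(), "-", "X")
  for (i in 1:50) {
    col <- sample(pool, sample(2:8, 1), replace = TRUE)
    expect_identical(column_identity_score(col), brute_column_identity(col))
  }
})

test_that("locus conservation is the mean over defined columns", {
  ident <- locus_alignment(c(t1 = "MKV", t2 = "MKV"), "id")
  expect_equal(locus_conservation(ident), 1.0)
  # columns "AAA" and "AAB": scores 1 and 1/3 -> mean 2/3
  loc <- locus_alignment(c(t1 = "AA", t2 = "AA", t3 = "AC"), "g")
  expect_equal(locus_conservation(loc), 2 / 3)
  # undefined columns are excluded, not averaged as zero
  gappy <- locus_alignment(c(t1 = "A-", t2 = "A-", t3 = "AX"), "g2")
  expect_equal(locus_conservation(gappy), 1.0)
  allgap <- locus_alignment(c(t1 = "-X", t2 = "X-"), "bad")
  expect_error(locus_conservation(allgap), "bad")

  # brute-force oracle on simulated loci
  ds <- generate_dataset(simulation_config(n_taxa = 6L, n_loci = 8L,
                                           locus_length_range = c(15L, 30L),
                                           occupancy_target = 0.7, seed = 21))
  for (loc in ds$collection$loci)
    expect_equal(locus_conservation(loc), brute_locus_conservation(loc))
})

test_that("ranking is descending, deterministic and tie-broken by locus id", {
  mk <- function(id, seqs) locus_alignment(seqs, id)
  # scores: g1 = 1.0, g2 = 0.5, g3 = 1.0 -> order g1, g3, g2
  coll <- orthogroup_collection(list(
    mk("g1", c(t1 = "AA", t2 = "AA")),
    mk("g2", c(t1 = "AC", t2 = "AA")),
    mk("g3", c(t1 = "CC", t2 = "CC"))))
  rk <- rank_by_conservation(coll)
  expect_equal(rk$locus_id, c("g1", "g3", "g2"))
  # input order does not matter
  rev_coll <- orthogroup_collection(rev(coll$loci))
  expect_equal(rank_by_conservation(rev_coll)$locus_id, rk$locus_id)
})

test_that("the ranking prefix holds the highest scores (sort oracle, 277 loci)", {
  ds <- dataset_277()
  rk <- rank_by_conservation(ds$collection)
  expect_false(is.unsorted(rev(rk$score)))
  top50 <- rk$locus_id[1:50]
  scores <- setNames(rk$score, rk$locus_id)
  expect_true(min(scores[top50]) >= max(scores[setdiff(names(scores), top50)]))
})

test_that("cumulative submatrices are nested ranking prefixes", {
  ds <- dataset_277()
  cum <- cumulative_submatrices(ds$collection, c(50, 100, 150, 200))
  expect_equal(unname(series_sizes(cum)), c(50L, 100L, 150L, 200L))
  for (k in 1:3)
    expect_true(all(locus_ids(cum$members[[k]]) %in%
                    locus_ids(cum$members[[k + 1]])))
  single <- cumulative_submatrices(ds$collection, 277)
  expect_equal(locus_ids(single$members[[1]]),
               rank_by_conservation(ds$collection)$locus_id)
  expect_error(cumulative_submatrices(ds$collection, c(100, 50)),
               "ascending")
  expect_error(cumulative_submatrices(ds$collection, c(50, 300)), "cut_points")
})

test_that("block submatrices partition the ranking into disjoint rank blocks", {
  ds <- dataset_277()
  blk <- block_submatrices(ds$collection, 50)
  expect_equal(unname(series_sizes(blk)), c(50L, 50L, 50L, 50L, 50L, 27L))
  expect_equal(names(blk$members), c("E", "F", "G", "H", "I", "J"))
  ids <- lapply(blk$members, locus_ids)
  expect_equal(sum(lengths(ids)), 277)
  expect_equal(anyDuplicated(unlist(ids)), 0)
  expect_setequal(unlist(ids), locus_ids(ds$collection))
  expect_error(block_submatrices(ds$collection, 0), "positive")

  hundred <- subset_collection(ds$collection, locus_ids(ds$collection)[1:100])
  expect_equal(unname(series_sizes(block_submatrices(hundred, 50))),
               c(50L, 50L))
})

test_that("every submatrix member concatenates into a consistent supermatrix", {
  ds <- generate_dataset(simulation_config(n_taxa = 8L, n_loci = 30L,
                                           locus_length_range = c(20L, 40L),
                                           occupancy_target = 0.8, seed = 5))
  blk <- block_submatrices(ds$collection, 10)
  for (m in blk$members) {
    sm <- concatenate_loci(m)
    expect_identical(sm$taxa, ds$collection$taxon_universe)
    expect_equal(sm$n_columns,
                 sum(vapply(m$loci, `[[`, 0, "n_columns")))
  }
})
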