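# a supermatrix built directly from residue rows
rows_matrix <- function(rows) {
  concatenate_loci(orthogroup_collection(list(
    locus_alignment(rows, "g1"))))
}

test_that("p-distances count mismatches over shared usable columns", {
  sm <- rows_matrix(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAGG", t4 = "AG-A",
                      t5 = "A--A"))
  dm <- p_distance_matrix(sm)
  expect_equal(dm$d["t1", "t2"], 0)          # identical rows
  expect_equal(dm$d["t1", "t3"], 0.5)        # AAAA vs AAGG
  expect_equal(dm$d["t4", "t5"], 0)          # 2 usable shared columns, equal
  expect_equal(dm$d["t3", "t5"], 0.5)        # columns 1 and 4: A/A, G/A
  expect_true(isSymmetric(dm$d))
  expect_equal(diag(dm$d), setNames(rep(0, 5), sm$taxa))
})

test_that("pairs sharing no usable column are undefined and rejected by NJ", {
  sm <- rows_matrix(c(t1 = "AC--", t2 = "AG--", t3 = "--GG", t4 = "A-G-"))
  dm <- p_distance_matrix(sm)
  expect_true(is.na(dm$d["t1", "t3"]))
  expect_error(neighbor_joining(dm), "undefined")
})

test_that("NJ recovers the topology behind an additive distance matrix", {
  t0 <- parse_newick("((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(t0)
  nj1 <- neighbor_joining(list(taxa = rownames(d), d = d))
  expect_equal(tree_bipartitions(nj1),
               canonical_split(c("C", "D"), LETTERS[1:4]))
  # recovered branch lengths reproduce the additive distances
  expect_equal(ape::cophenetic.phylo(nj1)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)

  # ultrametric 5-taxon case, checked against exhaustive least-squares fit
  skip_if_not_installed("phangorn")
  set.seed(41)
  t5 <- ape::rcoal(5)
  d5 <- ape::cophenetic.phylo(t5)
  nj5 <- neighbor_joining(list(taxa = rownames(d5), d = d5))
  best <- best_topologies_by_ls(d5, rownames(d5))
  expect_true(any(vapply(best, same_topology, logical(1), t2 = nj5)))
  expect_true(same_topology(nj5, t5))
})

test_that("NJ topology is invariant to taxon order and clamps negative branches", {
  set.seed(43)
  t0 <- ape::rtree(7)
  d <- ape::cophenetic.phylo(t0)
  nj1 <- neighbor_joining(list(taxa = rownames(d), d = d))
  perm <- sample(7)
  nj2 <- neighbor_joining(list(taxa = rownames(d)[perm],
                               d = d[perm, perm]))
  expect_true(same_topology(nj1, nj2))
  expect_true(all(nj1$edge.length >= 0))
  # total tree length is preserved by the clamp-and-transfer rule
  noisy <- d + matrix(runif(49, 0, 0.02), 7, 7)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  njn <- neighbor_joining(list(taxa = rownames(d), d = noisy))
  raw <- ape::nj(noisy)
  expect_true(all(njn$edge.length >= 0))
  expect_equal(sum(njn$edge.length), sum(raw$edge.length))
})

test_that("bootstrap replicates are seeded, deterministic and leave the RNG alone", {
  ds <- generate_dataset(simulation_config(n_taxa = 6L, n_loci = 10L,
                                           locus_length_range = c(40L, 80L),
                                           occupancy_target = 1, seed = 47))
  sm <- concatenate_loci(ds$collection)
  set.seed(999)
  state_before <- .Random.seed
  b1 <- bootstrap_trees(sm, 10, seed = 5)
  expect_identical(.Random.seed, state_before)
  b2 <- bootstrap_trees(sm, 10, seed = 5)
  expect_identical(vapply(b1, write_newick, ""), vapply(b2, write_newick, ""))
  expect_false(identical(vapply(bootstrap_trees(sm, 10, seed = 6),
                                write_newick, ""),
                         vapply(b1, write_newick, "")))
  expect_length(bootstrap_trees(sm, 1, seed = 1), 1)
})

test_that("bootstrap distances agree with the direct p-distance on degenerate resampling", {
  # a one-column matrix forces every replicate to resample that column,
  # so the bootstrap tree must equal the NJ tree of the plain p-distances
  # replicated over columns
  ds <- generate_dataset(simulation_config(n_taxa = 6L, n_loci = 4L,
                                           locus_length_range = c(50L, 50L),
                                           occupancy_target = 1,
                                           rate_lognormal_sigma = 0.01,
                                           seed = 53))
  sm <- concatenate_loci(ds$collection)
  ref <- neighbor_joining(p_distance_matrix(sm))
  cons <- bootstrap_trees(sm, 25, seed = 7)
  # strong signal, no missingness: most replicates match the point estimate
  agree <- mean(vapply(cons, same_topology, logical(1), t2 = ref))
  expect_gte(agree, 0.8)
})
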