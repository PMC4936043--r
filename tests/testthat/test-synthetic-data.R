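test_that("dataset generation is a pure function of the configuration", {
  cfg <- simulation_config(n_taxa = 6L, n_loci = 8L,
                           locus_length_range = c(20L, 40L), seed = 61)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1$collection$loci, `[[`, "sequences"),
                   lapply(d2$collection$loci, `[[`, "sequences"))
  expect_identical(d1$truth$rates, d2$truth$rates)
  expect_identical(d1$truth$presence, d2$truth$presence)
  # a different seed changes the data
  d3 <- generate_dataset(simulation_config(n_taxa = 6L, n_loci = 8L,
                                           locus_length_range = c(20L, 40L),
                                           seed = 62))
  expect_false(identical(d1$collection$loci$g0001$sequences,
                         d3$collection$loci$g0001$sequences))
})

test_that("the zero-rate limit yields identical sequences and conservation 1", {
  cfg <- simulation_config(tree = demo_tree(), seed = 1)
  set.seed(1)
  loc <- simulate_locus(cfg, rate = 1e-12, n_columns = 200)$alignment
  expect_equal(length(unique(loc$sequences)), 1)
  expect_equal(locus_conservation(loc), 1.0)
})

test_that("the saturation limit drives pairwise identity to the matching probability", {
  # long branches and high rate: residues become independent draws from
  # the stationary vector, so P(match) -> sum(pi^2)
  tr <- parse_newick("((A:5,B:5):5,(C:5,D:5):5);")
  cfg <- simulation_config(tree = tr, seed = 1)
  set.seed(67)
  loc <- simulate_locus(cfg, rate = 2, n_columns = 10000)$alignment
  expect_lt(abs(locus_conservation(loc) - sum(default_stationary_freqs()^2)),
            0.01)
})

test_that("tip compositions converge to the stationary vector without bias", {
  tr <- parse_newick("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
  cfg <- simulation_config(tree = tr, seed = 1)
  set.seed(71)
  loc <- simulate_locus(cfg, rate = 1, n_columns = 50000)$alignment
  sft <- taxon_state_frequencies(loc)
  dev <- abs(sweep(sft$frequencies, 2, default_stationary_freqs()))
  expect_lt(max(dev), 0.01)
})

test_that("biased taxa record and express their effective stationary vector", {
  cfg <- simulation_config(tree = demo_tree(), n_loci = 10L,
                           locus_length_range = c(200L, 400L),
                           occupancy_target = 1,
                           biased_taxa = list(Arcida_1 = list(state = "L",
                                                              delta = 0.3)),
                           seed = 73)
  ds <- generate_dataset(cfg)
  pi0 <- default_stationary_freqs()
  expect_equal(unname(ds$truth$taxon_freqs["Arcida_1", "L"]),
               unname(0.7 * pi0["L"] + 0.3))
  expect_equal(ds$truth$taxon_freqs["Mytilida_1", ], pi0)
  # the biased tip is enriched for 'L' relative to the others
  sm <- concatenate_loci(ds$collection)
  sft <- taxon_state_frequencies(sm)
  expect_gt(sft$frequencies["Arcida_1", "L"],
            max(sft$frequencies[setdiff(rownames(sft$frequencies),
                                        "Arcida_1"), "L"]))
})

test_that("missingness hits the occupancy target and never starves a locus", {
  cfg <- simulation_config(n_loci = 200L, locus_length_range = c(10L, 20L),
                           occupancy_target = 0.75, seed = 79)
  ds <- generate_dataset(cfg)
  p <- mean(ds$truth$presence)
  se <- sqrt(0.75 * 0.25 / length(ds$truth$presence))
  expect_lt(abs(p - 0.75), 3 * se)
  # presence mask and sequences agree
  for (id in locus_ids(ds$collection)[1:20]) {
    seqs <- ds$collection$loci[[id]]$sequences
    expect_identical(unname(grepl("[^-]", seqs)),
                     unname(ds$truth$presence[names(seqs), id]))
  }
  # occupancy 1 is the identity
  cfg1 <- simulation_config(n_loci = 5L, locus_length_range = c(10L, 20L),
                            occupancy_target = 1, seed = 83)
  expect_true(all(generate_dataset(cfg1)$truth$presence))
  # even harsh missingness keeps >= 4 taxa per locus
  cfg2 <- simulation_config(n_loci = 50L, locus_length_range = c(10L, 20L),
                            occupancy_target = 0.25, seed = 89)
  occ <- vapply(generate_dataset(cfg2)$collection$loci, taxon_occupancy,
                integer(1))
  expect_true(all(occ >= 4))
})

test_that("stricter occupancy thresholds retain fewer loci on lossy data", {
  ds <- generate_dataset(simulation_config(n_loci = 120L,
                                           locus_length_range = c(10L, 20L),
                                           occupancy_target = 0.75,
                                           seed = 97))
  n50 <- length(filter_by_min_taxa(ds$collection, 10L)$loci)
  n90 <- length(filter_by_min_taxa(ds$collection, 18L)$loci)
  expect_lt(n90, n50)
})

test_that("written datasets carry enough truth to rerun the analyses", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_taxa = 6L, n_loci = 6L,
                           locus_length_range = c(20L, 30L), seed = 101)
  ds <- generate_dataset(cfg, dir = dir)
  back <- read_orthogroup_dir(file.path(dir, "loci"))
  expect_equal(length(back$loci), 6)
  rates <- utils::read.delim(file.path(dir, "truth_rates.tsv"))
  expect_equal(rates$rate, ds$truth$rates$rate, tolerance = 1e-9)
  tr <- read_tree_set(file.path(dir, "true_tree.nwk"))[[1]]
  expect_true(same_topology(tr, ds$truth$tree))
})
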