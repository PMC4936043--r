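# shared in-code fixtures; heavier simulated datasets are cached so several
# test files can reuse them within one run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# three hand-built loci over a 4-taxon universe:
#   g1: all 4 taxa, 6 columns; g2: 3 taxa (t4 absent), 4 columns;
#   g3: 2 taxa + one all-gap row -> occupancy 2
tiny_collection <- function() {
  orthogroup_collection(list(
    locus_alignment(c(t1 = "ACDEFG", t2 = "ACDEFG", t3 = "ACDKFG",
                      t4 = "ACDKLG"), "g1"),
    locus_alignment(c(t1 = "MNPQ", t2 = "MNPQ", t3 = "MNPX"), "g2"),
    locus_alignment(c(t1 = "WY", t2 = "WY", t4 = "--"), "g3")),
    taxon_universe = c("t1", "t2", "t3", "t4"))
}

# default-condition simulated dataset (the study conditions of the
# generator): 20 taxa, 300 loci, sigma 0.7, occupancy 0.8
default_dataset <- function() {
  cached("default_ds", generate_dataset(simulation_config(seed = 7)))
}

# 277-locus fully-occupied dataset on the packaged demo tree, small loci
dataset_277 <- function() {
  cached("ds277", generate_dataset(simulation_config(
    tree = demo_tree(), n_loci = 277, locus_length_range = c(40L, 90L),
    occupancy_target = 1, seed = 277)))
}
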