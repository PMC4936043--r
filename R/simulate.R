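#' Default stationary amino-acid frequencies
#'
#' Empirical global amino-acid frequencies (the WAG equilibrium
#' composition), reordered to [aa_states()] and renormalized. These make
#' simulated sequences compositionally realistic rather than uniform.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
default_stationary_freqs <- function() {
  f <- c(A = 0.0866279, R = 0.0439720, N = 0.0390894, D = 0.0570451,
         C = 0.0193078, Q = 0.0367281, E = 0.0580589, G = 0.0832518,
         H = 0.0244313, I = 0.0484660, L = 0.0862090, K = 0.0620286,
         M = 0.0195027, F = 0.0384319, P = 0.0457631, S = 0.0695179,
         T = 0.0610127, W = 0.0143859, Y = 0.0352742, V = 0.0708956)
  f <- f[aa_states()]
  f / sum(f)
}

#' Simulation configuration
#'
#' Describes a synthetic orthogroup dataset: a species tree (branch
#' lengths in expected substitutions per site at rate multiplier 1),
#' per-locus lognormal rate multipliers with median 1, uniform locus
#' lengths, independent per-(locus, taxon) missingness, and optional
#' per-taxon compositional bias applied on terminal branches.
#'
#' @param tree Optional [ape::phylo] tree with branch lengths. When
#'   `NULL`, a pure-birth tree with `n_taxa` leaves is generated from the
#'   seed and rescaled to root-to-tip depth `tree_depth`.
#' @param n_taxa Number of leaves for the auto-generated tree.
#' @param n_loci Number of loci to simulate.
#' @param locus_length_range Integer pair: min and max columns per locus.
#' @param rate_lognormal_sigma Standard deviation of `log` rate
#'   multipliers (`r ~ lognormal`, median 1); controls the conservation
#'   spread that drives rate-sorted submatrices.
#' @param occupancy_target Probability in `(0, 1]` that a (locus, taxon)
#'   cell is sampled; 1 disables missingness.
#' @param biased_taxa Named list: taxon label -> `list(state =, delta =)`.
#'   On that taxon's terminal branch, substitutions draw from the mixture
#'   `(1 - delta) * pi + delta * e(state)`.
#' @param stationary_freqs Length-20 probability vector over
#'   [aa_states()].
#' @param tree_depth Root-to-tip depth for the auto-generated tree.
#' @param seed Integer seed; [generate_dataset()] is a pure function of
#'   the configuration including this seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tree = NULL, n_taxa = 20L, n_loci = 300L,
                              locus_length_range = c(100L, 600L),
                              rate_lognormal_sigma = 0.7,
                              occupancy_target = 0.8,
                              biased_taxa = list(),
                              stationary_freqs = default_stationary_freqs(),
                              tree_depth = 0.5, seed = 1L) {
  if (!is.null(tree)) stopifnot(inherits(tree, "phylo"))
  stopifnot(n_loci >= 1, length(locus_length_range) == 2,
            locus_length_range[1] >= 1,
            locus_length_range[2] >= locus_length_range[1],
            rate_lognormal_sigma > 0,
            occupancy_target > 0, occupancy_target <= 1,
            length(stationary_freqs) == 20, all(stationary_freqs > 0),
            tree_depth > 0)
  stationary_freqs <- stationary_freqs / sum(stationary_freqs)
  names(stationary_freqs) <- aa_states()
  for (tx in names(biased_taxa)) {
    bt <- biased_taxa[[tx]]
    if (!is.list(bt) || is.null(bt$state) || is.null(bt$delta) ||
        !(bt$state %in% aa_states()) || bt$delta < 0 || bt$delta >= 1)
      stop(sprintf("biased_taxa['%s'] must be list(state = <aa>, delta = [0,1))",
                   tx))
  }
  structure(list(tree = tree, n_taxa = as.integer(n_taxa),
                 n_loci = as.integer(n_loci),
                 locus_length_range = as.integer(locus_length_range),
                 rate_lognormal_sigma = rate_lognormal_sigma,
                 occupancy_target = occupancy_target,
                 biased_taxa = biased_taxa,
                 stationary_freqs = stationary_freqs,
                 tree_depth = tree_depth,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# run code with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# materialize the species tree of a config (consumes RNG when tree = NULL)
resolve_tree <- function(config) {
  if (!is.null(config$tree)) return(config$tree)
  tr <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$tree_depth / depth
  tr$tip.label <- sprintf("taxon%02d", seq_len(config$n_taxa))
  tr
}

# terminal-branch stationary vector for one taxon
biased_freqs <- function(pi, bias) {
  if (is.null(bias)) return(pi)
  out <- (1 - bias$delta) * pi
  i <- match(bias$state, aa_states())
  out[i] <- out[i] + bias$delta
  out
}

# evolve one locus down the tree: along a branch of length b at rate r,
# a site keeps the ancestral residue with probability exp(-r*b), otherwise
# redraws from the (possibly biased, on terminal branches) stationary vector
simulate_locus_core <- function(tree, rate, n_columns, pi, biased_taxa,
                                locus_id) {
  ntip <- length(tree$tip.label)
  states <- matrix(NA_integer_, ntip + tree$Nnode, n_columns)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, n_columns, replace = TRUE, prob = pi)
  tr <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    psub <- 1 - exp(-rate * tr$edge.length[e])
    sub <- stats::runif(n_columns) < psub
    s <- states[p, ]
    if (any(sub)) {
      pi_use <- if (ch <= ntip)
        biased_freqs(pi, biased_taxa[[tree$tip.label[ch]]]) else pi
      s[sub] <- sample.int(20L, sum(sub), replace = TRUE, prob = pi_use)
    }
    states[ch, ] <- s
  }
  aa <- aa_states()
  seqs <- vapply(seq_len(ntip),
                 function(i) paste(aa[states[i, ]], collapse = ""), "")
  names(seqs) <- tree$tip.label
  locus_alignment(seqs, locus_id = locus_id)
}

#' Simulate one locus
#'
#' Draws (from the ambient RNG) a rate multiplier and length where not
#' supplied, then evolves sequences down the configured tree. Mostly
#' useful for inspection; [generate_dataset()] is the seeded entry point.
#'
#' @param config A [simulation_config()].
#' @param locus_index Integer used to form the locus id.
#' @param rate Optional fixed rate multiplier.
#' @param n_columns Optional fixed locus length.
#' @param tree Optional resolved tree (defaults to the config's tree;
#'   required in practice when `config$tree` is `NULL`).
#' @return List with `alignment` (a [locus_alignment()]), `rate` and
#'   `n_columns`.
#' @export
simulate_locus <- function(config, locus_index = 1L, rate = NULL,
                           n_columns = NULL, tree = config$tree) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(tree)) tree <- resolve_tree(config)
  if (is.null(rate))
    rate <- exp(stats::rnorm(1, 0, config$rate_lognormal_sigma))
  if (is.null(n_columns)) {
    rng <- config$locus_length_range
    n_columns <- sample(seq(rng[1], rng[2]), 1)
  }
  aln <- simulate_locus_core(tree, rate, n_columns, config$stationary_freqs,
                             config$biased_taxa,
                             sprintf("g%04d", locus_index))
  list(alignment = aln, rate = rate, n_columns = n_columns)
}

#' Delete whole (locus, taxon) cells to a target occupancy
#'
#' Each (locus, taxon) pair is independently dropped (its sequence
#' replaced by all `'-'`) with probability `1 - occupancy_target`,
#' emulating unsampled genes in transcriptome datasets. Draws for a locus
#' are redone until at least four taxa remain, up to `retry_cap` attempts.
#' Uses the ambient RNG; [generate_dataset()] applies it inside its seeded
#' scope.
#'
#' @param dataset A [generate_dataset()] result.
#' @param occupancy_target Probability in `(0, 1]` that a cell is kept.
#' @param retry_cap Maximum redraws per locus.
#' @return The modified `simulated_dataset` (collection and truth mask
#'   updated).
#' @export
apply_missingness <- function(dataset, occupancy_target, retry_cap = 100L) {
  stopifnot(inherits(dataset, "simulated_dataset"),
            occupancy_target > 0, occupancy_target <= 1)
  if (occupancy_target == 1) return(dataset)
  coll <- dataset$collection
  pres <- dataset$truth$presence
  for (lid in locus_ids(coll)) {
    loc <- coll$loci[[lid]]
    nt <- length(loc$sequences)
    tries <- 0L
    repeat {
      keep <- stats::runif(nt) < occupancy_target
      if (sum(keep) >= 4) break
      tries <- tries + 1L
      if (tries >= retry_cap)
        stop(sprintf(
          "locus '%s': could not retain 4 taxa at occupancy %.3f", lid,
          occupancy_target))
    }
    gaprow <- strrep(.GAP, loc$n_columns)
    loc$sequences[!keep] <- gaprow
    coll$loci[[lid]] <- loc
    pres[names(loc$sequences), lid] <- keep
  }
  dataset$collection <- coll
  dataset$truth$presence <- pres
  dataset
}

#' Generate a synthetic orthogroup dataset with ground truth
#'
#' Seeds the RNG from `config$seed`, resolves the species tree, draws
#' per-locus rate multipliers and lengths, simulates every locus, applies
#' missingness, and returns the collection together with the truth needed
#' to evaluate the pipeline: true rates, the presence mask, the generating
#' tree, and each taxon's effective terminal-branch stationary vector.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, per-locus FASTA files, the
#'   tree and truth tables are written there.
#' @return A `simulated_dataset`: list with `collection`, `truth`
#'   (`rates`, `presence`, `tree`, `taxon_freqs`) and `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dataset <- with_seed(config$seed, {
    tree <- resolve_tree(config)
    n <- config$n_loci
    rates <- exp(stats::rnorm(n, 0, config$rate_lognormal_sigma))
    rng <- config$locus_length_range
    lens <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
    ids <- sprintf("g%04d", seq_len(n))
    loci <- lapply(seq_len(n), function(i)
      simulate_locus_core(tree, rates[i], lens[i], config$stationary_freqs,
                          config$biased_taxa, ids[i]))
    coll <- orthogroup_collection(loci, taxon_universe = tree$tip.label)
    pres <- matrix(TRUE, length(tree$tip.label), n,
                   dimnames = list(tree$tip.label, ids))
    tf <- t(vapply(tree$tip.label, function(tx)
      biased_freqs(config$stationary_freqs, config$biased_taxa[[tx]]),
      numeric(20)))
    colnames(tf) <- aa_states()
    ds <- structure(
      list(collection = coll,
           truth = list(rates = data.frame(locus_id = ids, rate = rates,
                                           n_columns = lens,
                                           stringsAsFactors = FALSE),
                        presence = pres, tree = tree, taxon_freqs = tf),
           config = config),
      class = "simulated_dataset")
    apply_missingness(ds, config$occupancy_target)
  })
  if (!is.null(dir)) write_dataset(dataset, dir)
  dataset
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d loci, %d taxa, mean occupancy %.3f, seed %d\n",
    length(x$collection$loci), length(x$collection$taxon_universe),
    mean(x$truth$presence), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset (FASTA loci + truth tables)
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_orthogroup_dir(dataset$collection, file.path(dir, "loci"))
  utils::write.table(dataset$truth$rates,
                     file.path(dir, "truth_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pres <- data.frame(taxon = rownames(dataset$truth$presence),
                     dataset$truth$presence * 1L, check.names = FALSE)
  utils::write.table(pres, file.path(dir, "truth_presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$truth$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}

#' Packaged demonstration tree (synthetic)
#'
#' A 20-leaf synthetic tree of five 4-leaf clades, labelled after the five
#' pteriomorphian orders, with the topology
#' `(Arcida, ((Mytilida, Ostreida), (Limida, Pectinida)))`. Useful for
#' support-trajectory demonstrations where clade hypotheses need names.
#'
#' @return An [ape::phylo] tree.
#' @export
demo_tree <- function() {
  parse_newick(readLines(system.file("extdata",
                                     "demo_tree_5clades_synthetic.nwk",
                                     package = "pteriomatrix"),
                         warn = FALSE))
}

#' Packaged demonstration clade hypotheses (synthetic)
#'
#' Hypotheses matching [demo_tree()]: basal Arcida (monophyly of all other
#' clades), Mytilida + Ostreida, Limida + Pectinida, and monophyly of
#' Mytilida.
#'
#' @return Named list of [clade_hypothesis()] objects.
#' @export
demo_hypotheses <- function() {
  read_hypotheses(system.file("extdata", "demo_hypotheses_synthetic.tsv",
                              package = "pteriomatrix"))
}
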