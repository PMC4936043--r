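---
title: "Supermatrix engineering: occupancy, rate sorting, RCFV and support trajectories"
author: "pteriomatrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supermatrix engineering: occupancy, rate sorting, RCFV and support trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pteriomatrix)
```

## The problem this package addresses

Phylogenomic studies of difficult nodes — deep inter-ordinal splits such
as those among the pteriomorphian bivalves, which motivated this
package's design — rarely rest on one concatenated matrix. The robust
practice is to engineer a *family* of matrices from the same orthogroup
pool and ask whether contested clades keep their support across all of
them:

1. vary the **gene-occupancy threshold** (how many taxa a locus must be
   sampled for) to trade matrix size against completeness;
2. sort loci by a topology-agnostic **evolutionary-rate proxy** and
   analyse both nested prefixes of the ranking (slow loci always
   included, faster ones added incrementally) and disjoint rank blocks
   (each rate slice on its own);
3. screen the preferred matrix for **compositional heterogeneity**
   among taxa, which can mislead tree inference;
4. trace each clade hypothesis's **bootstrap support across the whole
   matrix series**.

`pteriomatrix` implements these four operations plus the plumbing they
need (FASTA/PHYLIP/partition/newick I/O, a seeded simulator with ground
truth, and a minimal NJ bootstrap backend), so the entire workflow is a
deterministic function of input files and a seed.

## Models and statistics

### Gene occupancy

A taxon counts as sampled for a locus if its row contains at least one
non-gap character. A row consisting only of `X` (present but ambiguous
residues) therefore counts as sampled — occupancy describes gene
*sampling*, not residue quality — whereas an all-gap row does not. This
is one operationalization among several possible (one could require a
minimum fraction of non-gap residues); it is the simplest rule that
distinguishes "unsampled" from "sequenced badly", and it is applied
consistently by the filter, the occupancy report and the simulator's
missingness mask.

Thresholds are expressed as minimum taxon counts. Subset operations
preserve the parent taxon universe: a taxon that loses all its loci in
some submatrix still receives an (all-gap) row, so every matrix in a
series shares one leaf set and trajectory comparisons never silently
prune taxa. (All-gap rows make pairwise distances undefined; the tree
backend refuses such matrices rather than guessing.)

### The conservation score as a rate proxy

For column $c$ with $m_c \ge 2$ usable residues (non-gap, non-`X`), the
column score is the fraction of the $\binom{m_c}{2}$ unordered residue
pairs that are identical; columns with $m_c < 2$ are undefined and
excluded. The locus score is the unweighted mean over defined columns.
Two deliberate choices:

* **Unweighted mean, not accumulated sum.** The score is scale-free:
  a 600-column locus and a 100-column locus with the same per-column
  identity get the same score, so the ranking reflects rate, not
  length. Tools that accumulate conservation values per locus weight by
  length; we do not aim for bit-level parity with any of them.
* **`X` is excluded from pairs.** An unknown residue can neither match
  nor mismatch; counting it either way would bias scores for
  low-quality taxa.

Ties in the ranking are broken by ascending locus id in the C locale,
making the ranking reproducible across platforms.

The cumulative series takes ranking prefixes at cut points (default 50,
100, 150, 200 — multiples of the block size, chosen to align the two
series on one grid; the cut points are configurable and nothing
downstream depends on the default). The block series tiles the ranking
into consecutive blocks of 50 (default) with the remainder in the final
block; a 277-locus pool thus yields blocks of 50, 50, 50, 50, 50 and
27. With three occupancy tiers, four cuts and six blocks, a run
produces the classic 13-matrix layout.

### RCFV

With $f_{s,t}$ the empirical frequency of amino acid $s$ among the
usable residues of taxon $t$, $\bar f_s$ the mean over the $n$ taxa,
each (state, taxon) pair contributes $|f_{s,t}-\bar f_s|/n$; sums over
states give per-taxon tRCFV, over taxa per-state csRCFV, and over both
the total. Normalizing by the number of taxa (rather than by matrix
length) keeps per-taxon and per-state values on a common, small scale.
Gaps and `X` are excluded from the frequencies, so missing data produce
no spurious compositional signal; a taxon with *no* usable residues is
flagged and excluded with a warning rather than averaged in as zeros.
The two groupings are the same double sum, and the report checks that
identity to $10^{-9}$.

### Clade support

A hypothesis is a named taxon set, read as the unrooted bipartition
(set | complement). Bipartitions are canonicalized as the side not
containing a fixed reference taxon, which makes the support count
invariant to rerooting and newick rotation. Trees must share an
identical leaf set; the package never prunes to a shared subset,
because silent pruning can turn "hypothesis refuted" into "hypothesis
untestable" without anyone noticing. Trivial bipartitions (singleton or
all-but-one sets) are rejected. Support is reported in $[0,1]$; the CLI
prints percentages, matching bootstrap-support convention.

### The NJ bootstrap backend

The backend is p-distance (mismatches over shared usable columns) plus
Saitou–Nei neighbour joining, with column resampling for bootstraps. It
exists so the trajectory machinery can be exercised end-to-end and
tested against simulations at desk scale; real analyses should use
likelihood or Bayesian inference and feed the resulting tree sets in as
newick files. Numerical details:

* bootstrap distances are computed as weighted per-column mismatch
  sums (resampling multiplicities as weights), one matrix product per
  replicate, after a single pass over the alignment;
* negative NJ branch lengths are clamped to zero with the deficit
  moved to the sister branch, preserving path lengths through the
  parent node; the count of clamped edges is kept as a tree attribute;
* taxon pairs with no shared usable column yield undefined distances;
  replicates that produce any are redrawn (up to a cap of 100), and
  point estimates fail loudly;
* `bootstrap_trees()` seeds the RNG itself and restores the caller's
  RNG state, so a (matrix, replicates, seed) triple always produces
  byte-identical newick output.

## The simulator: what it emulates, and what it does not

`generate_dataset()` evolves each locus down a species tree under a
20-state model with equal exchangeabilities and arbitrary stationary
frequencies $\pi$ (an F81-style generalization of the Poisson model).
This admits an exact closed-form transition along a branch of length
$b$ at locus rate $r$: a site retains the ancestral residue with
probability $e^{-rb}$ and otherwise redraws from $\pi$. Exactness
matters — the saturation limit of pairwise identity is analytically
$\sum_s \pi_s^2$, which the test suite checks directly.

Default study conditions (chosen once, as a realistic desk-scale
emulation of a transcriptome phylogenomics dataset):

| parameter | default | rationale |
|---|---|---|
| taxa | 20 | large enough for non-trivial bipartitions, small enough for seconds-scale tests |
| loci | 300 | same order as a 75%-occupancy transcriptome matrix |
| locus length | uniform 100–600 aa | typical orthogroup alignment lengths |
| rate multipliers | lognormal, median 1, $\sigma = 0.7$ | median 1 keeps branch lengths interpretable; $\sigma$ spreads rates ~25-fold across the central 95% |
| occupancy | 0.8 | mid-range transcriptome completeness |
| stationary $\pi$ | WAG equilibrium composition | realistic amino-acid usage rather than uniform |
| tree | seeded pure-birth, depth 0.5 | substitutions/site at rate 1 from root to tip |

Compositional bias for a taxon is applied on its terminal branch by
substituting from $\pi' = (1-\delta)\pi + \delta e_s$ for bias state
$s$; the truth record stores each taxon's effective $\pi'$ so recovery
experiments need no re-simulation. Missingness deletes whole
(locus, taxon) cells independently with probability one minus the
occupancy target, redrawing a locus until at least four taxa survive —
matching the fact that real occupancy structure arises gene-wise
(failed assembly or orthology assignment), not residue-wise.

A packaged fixture tree (`demo_tree()`, five 4-leaf clades named after
the five pteriomorphian orders, with `demo_hypotheses()` to match) is
used where experiments need named clades and uniformly decent terminal
branch lengths: the compositional-bias recovery experiment runs 20
seeded replicates of a 60-locus dataset on this tree, and the
trajectory experiment a 120-locus dataset with 100 bootstrap
replicates. These sizes were fixed as the package's desk-scale
experimental design; the test suite checks (among much else) that the
conservation ranking recovers the true rate order (Spearman $\le -0.9$
at the default conditions) and that a $\delta = 0.2$ leucine bias puts
the biased taxon at the top of the tRCFV ranking in at least 95% of
replicates.

What the simulator deliberately does **not** emulate: indels (gaps
arise only from gene-level missingness), alignment error, heterotachy
(a locus's rate is constant across lineages), site-rate variation
within a locus, codon structure, and empirical exchangeabilities (WAG
supplies only the stationary composition, not the exchange matrix).
Consequently, passing tests demonstrate that the *machinery* —
ranking, bookkeeping, screening, trajectory assembly — behaves
correctly under the model's assumptions; they do not certify that the
percent-identity proxy or RCFV screen is adequate for any particular
real dataset, where alignment artefacts and heterotachy add noise the
simulation lacks.

## Degenerate inputs and numerical conventions

* Internal coordinates are 0-based half-open; partition files are
  written 1-based inclusive (the RAxML dialect), and the writer
  verifies that ranges tile the matrix exactly.
* `?` is normalized to `-` on input; `-` is the single missing symbol
  throughout; `X` is a present residue of unknown identity.
* Taxon labels with whitespace are rejected at construction, keeping
  FASTA/PHYLIP/newick interchange bit-exact.
* Loci with no defined column cannot be scored and raise an error
  naming the locus; columns with fewer than two usable residues are
  skipped silently (they carry no information, and erroring would make
  gappy but legitimate loci unusable).
* All randomized entry points (`generate_dataset()`,
  `bootstrap_trees()`, `run_pipeline()`) are driven by explicit seeds
  and leave the caller's RNG state untouched; the pipeline manifest
  records the seed and an MD5 checksum of every artifact, and reruns
  with identical inputs are checksum-identical.

## A small end-to-end run

```{r pipeline, eval = FALSE}
out <- tempfile("pteriomatrix_run_")
cfg <- pipeline_config(
  out_dir = out,
  simulation = simulation_config(tree = demo_tree(), n_loci = 277,
                                 locus_length_range = c(40, 90),
                                 occupancy_target = 1, seed = 11),
  bootstrap_replicates = 50,
  hypotheses = demo_hypotheses(),
  seed = 11)
manifest <- run_pipeline(cfg)
manifest$n_matrices          # 13: three tiers + A-D + E-J
manifest$block_sizes         # 50 50 50 50 50 27
read.delim(file.path(out, "trajectory_Mytilida_Ostreida_cumulative.tsv"))
```

The run writes, per matrix, FASTA + relaxed PHYLIP + partition files;
per hypothesis, cumulative and block trajectory TSVs (the cumulative
series ends at the full middle-tier matrix); the conservation ranking,
the occupancy report, the RCFV report of the middle tier, all bootstrap
tree sets, and `manifest.json`.

## Known limitations

* The rate proxy saturates: above roughly one substitution per site,
  pairwise identity flattens toward $\sum_s \pi_s^2$ and ceases to
  discriminate among fast loci. Rankings within the fastest block are
  correspondingly noisy.
* RCFV has no significance test here; it is a descriptive screen, and
  its scale depends on taxon count and sequence length. Compare values
  within a matrix, not across studies.
* The NJ backend ignores among-site rate variation and multiple hits;
  its bootstrap supports are optimistic on clean simulated data and
  are not a substitute for model-based support values on real data.
* Very low occupancy combined with short loci can leave taxon pairs
  with no shared columns; the backend surfaces this as an error rather
  than imputing distances.
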