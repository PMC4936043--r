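# independent oracles, kept deliberately naive

# column identity by exhaustive enumeration of unordered residue pairs
brute_column_identity <- function(column) {
  usable <- column[!column %in% c("-", "X")]
  if (length(usable) < 2) return(NA_real_)
  prs <- utils::combn(usable, 2)
  mean(prs[1, ] == prs[2, ])
}

# locus conservation as the mean of brute-force column scores
brute_locus_conservation <- function(locus) {
  m <- do.call(rbind, strsplit(unname(locus$sequences), ""))
  sc <- apply(m, 2, brute_column_identity)
  mean(sc[!is.na(sc)])
}

# RCFV total straight from the definition, loop form
brute_rcfv_total <- function(freq) {
  n <- nrow(freq)
  fbar <- colMeans(freq)
  tot <- 0
  for (t in seq_len(n)) for (s in seq_len(ncol(freq)))
    tot <- tot + abs(freq[t, s] - fbar[s]) / n
  unname(tot)
}

# least-squares branch-length fit of a fixed topology to a distance
# matrix; returns the residual sum of squares (branch lengths free to be
# negative, so an additive matrix on the true topology fits exactly)
ls_topology_rss <- function(topology, d) {
  labs <- topology$tip.label
  n <- length(labs)
  pairs <- t(utils::combn(seq_len(n), 2))
  ne <- nrow(topology$edge)
  X <- matrix(0, nrow(pairs), ne)
  # tips below each edge's child node
  below <- function(node) {
    if (node <= n) return(node)
    kids <- topology$edge[topology$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  for (e in seq_len(ne)) {
    tips <- below(topology$edge[e, 2])
    X[, e] <- xor(pairs[, 1] %in% tips, pairs[, 2] %in% tips)
  }
  y <- d[pairs]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# best unrooted topologies for a distance matrix by enumerating all of
# them and ranking by least-squares RSS (feasible for <= 7 leaves)
best_topologies_by_ls <- function(d, labels) {
  allt <- phangorn::allTrees(length(labels), rooted = FALSE,
                             tip.label = labels)
  rss <- vapply(allt, ls_topology_rss, numeric(1), d = d)
  allt[rss < min(rss) + 1e-9]
}

# set equality of the non-trivial bipartitions of two trees
same_topology <- function(t1, t2) {
  setequal(tree_bipartitions(t1), tree_bipartitions(t2))
}
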