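#' A named clade hypothesis
#'
#' A clade hypothesis is a named taxon set, interpreted on unrooted trees
#' as the bipartition `taxon_set | complement`. The set must be a proper
#' subset of the analysis taxa.
#'
#' @param hypothesis_id Short identifier, e.g. `"Mytilida_Ostreida"`.
#' @param taxon_set Non-empty character vector of taxon labels.
#' @return An object of class `clade_hypothesis`.
#' @export
clade_hypothesis <- function(hypothesis_id, taxon_set) {
  taxon_set <- unique(as.character(taxon_set))
  if (length(taxon_set) == 0) stop("taxon_set must be non-empty")
  structure(list(hypothesis_id = as.character(hypothesis_id)[1],
                 taxon_set = taxon_set),
            class = "clade_hypothesis")
}

# canonical key for the bipartition side not containing the reference
# taxon (the alphabetically smallest leaf label)
canonical_split <- function(side, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = ";")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge, canonicalized as the side that does
#' not contain a fixed reference taxon. Trees with fewer than four leaves,
#' and star trees, have none.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of canonical split keys (taxa sorted, joined
#'   by `";"`).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4) return(character(0))
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(part) {
    k <- length(part)
    if (k < 2 || k > n - 2) return(NA_character_)
    canonical_split(labs[part], labs)
  }, NA_character_)
  unique(keys[!is.na(keys)])
}

#' Frequency of a clade hypothesis in a set of trees
#'
#' Fraction of trees whose bipartition set contains the hypothesis split.
#' All trees must share an identical leaf set containing the hypothesis
#' taxa; no silent pruning to shared subsets is performed. Hypotheses that
#' reduce to a trivial bipartition (single taxon, or all-but-one) are
#' rejected.
#'
#' @param trees A `multiPhylo` or list of [ape::phylo] trees.
#' @param hypothesis A [clade_hypothesis()].
#' @return A value in `[0, 1]`.
#' @export
clade_frequency <- function(trees, hypothesis) {
  stopifnot(inherits(hypothesis, "clade_hypothesis"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("empty tree set")
  labs <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    li <- sort(trees[[i]]$tip.label)
    if (!identical(li, labs)) {
      dd <- c(setdiff(labs, li), setdiff(li, labs))
      stop(sprintf("leaf-set mismatch across trees; symmetric difference: %s",
                   paste(dd, collapse = ", ")))
    }
  }
  miss <- setdiff(hypothesis$taxon_set, labs)
  if (length(miss) > 0)
    stop(sprintf("hypothesis taxa absent from trees: %s",
                 paste(miss, collapse = ", ")))
  k <- length(hypothesis$taxon_set)
  if (k < 2 || k > length(labs) - 2)
    stop(sprintf("hypothesis '%s' is a trivial bipartition",
                 hypothesis$hypothesis_id))
  key <- canonical_split(hypothesis$taxon_set, labs)
  mean(vapply(trees, function(tr) key %in% tree_bipartitions(tr),
              logical(1)))
}

#' Support trajectory of a hypothesis across a matrix series
#'
#' Evaluates [clade_frequency()] once per tree set, preserving the order
#' of the series — e.g. cumulative matrices A–D followed by the full
#' matrix, or blocks E–J.
#'
#' @param tree_sets Named list: matrix label -> list of trees.
#' @param hypothesis A [clade_hypothesis()].
#' @return A `support_trajectory` data frame with columns `matrix_label`,
#'   `support` (in `[0, 1]`) and `n_trees`.
#' @export
support_trajectory <- function(tree_sets, hypothesis) {
  if (length(tree_sets) == 0) stop("need at least one tree set")
  if (is.null(names(tree_sets)) || any(!nzchar(names(tree_sets))))
    stop("tree_sets must be named by matrix label")
  out <- data.frame(
    matrix_label = names(tree_sets),
    support = vapply(tree_sets, clade_frequency, numeric(1),
                     hypothesis = hypothesis),
    n_trees = vapply(tree_sets, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hypothesis_id") <- hypothesis$hypothesis_id
  class(out) <- c("support_trajectory", "data.frame")
  out
}

#' @export
plot.support_trajectory <- function(x, type = "b", pch = 18,
                                    ylim = c(0, 1), ...) {
  plot(seq_len(nrow(x)), x$support, type = type, pch = pch, ylim = ylim,
       xaxt = "n", xlab = "matrix", ylab = "bootstrap frequency",
       main = attr(x, "hypothesis_id"), ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$matrix_label)
  invisible(x)
}

#' Read clade hypotheses from a tab-separated file
#'
#' Each line: `hypothesis_id<TAB>comma-separated taxa`. Blank lines and
#' `#` comments are ignored.
#'
#' @param path Path to the hypothesis file.
#' @return Named list of [clade_hypothesis()] objects.
#' @export
read_hypotheses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop(sprintf("no hypotheses in '%s'", path))
  hyps <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed hypothesis line: '%s'", ln))
    clade_hypothesis(parts[1], trimws(strsplit(parts[2], ",")[[1]]))
  })
  names(hyps) <- vapply(hyps, `[[`, "", "hypothesis_id")
  hyps
}

#' Write a support trajectory as TSV
#' @param trajectory A [support_trajectory()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$hypothesis_id <- attr(trajectory, "hypothesis_id")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
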