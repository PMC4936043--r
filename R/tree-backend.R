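#' Uncorrected pairwise distances of a supermatrix
#'
#' p-distance between two taxa: mismatches divided by the number of shared
#' usable columns (both residues non-gap, non-`'X'`). Pairs with no shared
#' usable column are recorded as `NA` and rejected later by
#' [neighbor_joining()] rather than silently imputed.
#'
#' @param matrix A [supermatrix][concatenate_loci()].
#' @return A `p_distance_matrix`: list with `taxa` and the symmetric
#'   matrix `d` (zero diagonal, `NA` for undefined pairs).
#' @export
p_distance_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "supermatrix"))
  codes <- seq_code_matrix(matrix$sequences)
  n <- nrow(codes)
  if (n < 4) stop("need at least 4 taxa")
  d <- matrix(0, n, n, dimnames = list(matrix$taxa, matrix$taxa))
  for (i in seq_len(n - 1)) {
    xi <- codes[i, ]
    for (j in (i + 1):n) {
      xj <- codes[j, ]
      us <- !is.na(xi) & !is.na(xj)
      nu <- sum(us)
      d[i, j] <- d[j, i] <-
        if (nu == 0) NA_real_ else sum(xi[us] != xj[us]) / nu
    }
  }
  structure(list(taxa = matrix$taxa, d = d), class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat(sprintf("<p_distance_matrix> %d taxa, %d undefined pairs\n",
              length(x$taxa), sum(is.na(x$d)) / 2))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining (via [ape::nj()]) on a complete distance
#' matrix. Negative branch lengths — an occasional NJ artefact — are
#' clamped to zero with the deficit transferred to the sister branch, so
#' path lengths through the parent node are preserved; the number of
#' clamped edges is recorded in `attr(tree, "clamped_edges")`. This backend
#' exists so downstream support machinery can run end-to-end at desk
#' scale; it is not a substitute for likelihood or Bayesian inference.
#'
#' @param dm A [p_distance_matrix()] (or any list with `taxa` and `d`).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  d <- dm$d
  if (anyNA(d))
    stop("distance matrix has undefined entries; cannot run neighbour joining")
  if (length(dm$taxa) < 4) stop("need at least 4 taxa")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib) > 0)
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  attr(tr, "clamped_edges") <- length(neg)
  tr
}

#' Column-bootstrap NJ trees for a supermatrix
#'
#' Each replicate resamples `n_columns` columns with replacement from the
#' whole concatenation (ignoring partition boundaries, as in the standard
#' nonparametric bootstrap), recomputes p-distances and runs
#' [neighbor_joining()]. A replicate whose distance matrix has undefined
#' entries is redrawn, up to `retry_cap` attempts. The RNG state is seeded
#' from `seed` and restored on exit, so identical seeds give identical
#' trees.
#'
#' Distances over resampled columns are computed as weighted per-column
#' mismatch sums (column multiplicities as weights), which makes replicates
#' cheap after one pass over the matrix.
#'
#' @param matrix A [supermatrix][concatenate_loci()].
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param retry_cap Maximum redraws per replicate before failing.
#' @return A `multiPhylo` list of unrooted trees.
#' @export
bootstrap_trees <- function(matrix, n_replicates, seed, retry_cap = 100L) {
  stopifnot(inherits(matrix, "supermatrix"), n_replicates >= 1)
  codes <- seq_code_matrix(matrix$sequences)
  n <- nrow(codes)
  if (n < 4) stop("need at least 4 taxa")
  L <- ncol(codes)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  np <- nrow(pairs)
  mism <- matrix(0, L, np)
  usab <- matrix(0, L, np)
  for (p in seq_len(np)) {
    xi <- codes[pairs[p, 1], ]
    xj <- codes[pairs[p, 2], ]
    us <- !is.na(xi) & !is.na(xj)
    mm <- xi != xj
    mm[!us] <- FALSE
    usab[, p] <- us
    mism[, p] <- mm
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tries <- 0L
    repeat {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      den <- as.vector(w %*% usab)
      if (all(den > 0)) break
      tries <- tries + 1L
      if (tries >= retry_cap)
        stop("bootstrap replicate has taxon pairs with no shared columns")
    }
    num <- as.vector(w %*% mism)
    d <- matrix(0, n, n, dimnames = list(matrix$taxa, matrix$taxa))
    d[pairs] <- num / den
    d <- d + t(d)
    trees[[r]] <- neighbor_joining(list(taxa = matrix$taxa, d = d))
  }
  structure(trees, class = "multiPhylo", seed = seed)
}
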