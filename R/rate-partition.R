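#' Percent pairwise identity of one alignment column
#'
#' Fraction of unordered pairs of usable residues (non-gap, non-`'X'`)
#' that are identical. Columns with fewer than two usable residues carry no
#' pairwise information and return `NA` (excluded, not an error).
#'
#' @param column Character vector of single residues (one per taxon).
#' @return A value in `[0, 1]`, or `NA_real_` for an undefined column.
#' @export
#' @examples
#' column_identity_score(c("A", "A", "A", "B"))  # 3 of 6 pairs -> 0.5
column_identity_score <- function(column) {
  res <- toupper(column)
  res <- res[res != .GAP & res != .AMBIG]
  m <- length(res)
  if (m < 2) return(NA_real_)
  cnt <- table(res)
  sum(cnt * (cnt - 1) / 2) / (m * (m - 1) / 2)
}

# vectorized column scores for a taxa x columns integer-code matrix
column_scores_codes <- function(codes) {
  m <- colSums(!is.na(codes))
  ident <- numeric(ncol(codes))
  for (s in seq_len(20L)) {
    cs <- colSums(codes == s, na.rm = TRUE)
    ident <- ident + cs * (cs - 1) / 2
  }
  ifelse(m >= 2, ident / (m * (m - 1) / 2), NA_real_)
}

#' Conservation score of a locus (evolutionary-rate proxy)
#'
#' Unweighted arithmetic mean of the defined [column_identity_score()]s of
#' the locus. High values mean slow-evolving (conserved) loci; the score is
#' agnostic to tree topology, which is exactly why it serves as a rate
#' proxy for locus sorting. Length-independence is deliberate: the mean
#' over defined columns, not a length-weighted accumulation.
#'
#' @param locus A [locus_alignment()] with at least two taxa.
#' @return A value in `[0, 1]`.
#' @export
locus_conservation <- function(locus) {
  stopifnot(inherits(locus, "locus_alignment"))
  if (length(locus$sequences) < 2)
    stop(sprintf("locus '%s' has fewer than 2 taxa", locus$locus_id))
  sc <- column_scores_codes(seq_code_matrix(locus$sequences))
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0)
    stop(sprintf("locus '%s' has no column with >= 2 usable residues",
                 locus$locus_id))
  mean(sc)
}

#' Rank loci from most to least conserved
#'
#' Orders loci by descending [locus_conservation()]; ties are broken by
#' ascending locus id (C-locale) so the ranking is fully deterministic.
#'
#' @param collection An [orthogroup_collection()].
#' @return A `conservation_ranking` data frame with columns `locus_id`,
#'   `score` and `rank`, most conserved first.
#' @export
rank_by_conservation <- function(collection) {
  stopifnot(inherits(collection, "orthogroup_collection"))
  score <- vapply(collection$loci, locus_conservation, numeric(1))
  ids <- locus_ids(collection)
  o <- order(-score, ids, method = "radix")
  out <- data.frame(locus_id = ids[o], score = unname(score[o]),
                    rank = seq_along(o), stringsAsFactors = FALSE)
  class(out) <- c("conservation_ranking", "data.frame")
  out
}

new_submatrix_series <- function(series_id, members, parameters) {
  structure(list(series_id = series_id, members = members,
                 parameters = parameters),
            class = "submatrix_series")
}

#' @export
print.submatrix_series <- function(x, ...) {
  sizes <- vapply(x$members, function(m) length(m$loci), integer(1))
  cat(sprintf("<submatrix_series> %s: %d members (%s loci)\n",
              x$series_id, length(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Cumulative submatrices by incremental locus addition
#'
#' Member *k* contains the top `cut_points[k]` loci of the conservation
#' ranking, so members are strictly nested prefixes (slowest-evolving loci
#' are always included, later members add progressively faster ones). The
#' full collection is conventionally appended as the last point when a
#' support trajectory is assembled, not here.
#'
#' @param collection An [orthogroup_collection()].
#' @param cut_points Strictly ascending integers, each `<=` the number of
#'   loci.
#' @param ranking Optional precomputed [rank_by_conservation()] result.
#' @param labels Member labels; defaults to `LETTERS` (`A`, `B`, ...).
#' @return A `submatrix_series` with `series_id = "cumulative"`.
#' @export
cumulative_submatrices <- function(collection, cut_points,
                                   ranking = rank_by_conservation(collection),
                                   labels = LETTERS[seq_along(cut_points)]) {
  n <- length(collection$loci)
  cut_points <- as.integer(cut_points)
  if (length(cut_points) == 0 || any(diff(cut_points) <= 0))
    stop("cut_points must be strictly ascending")
  if (cut_points[1] < 1 || cut_points[length(cut_points)] > n)
    stop(sprintf("cut_points must lie in [1, %d]", n))
  members <- lapply(cut_points, function(k)
    subset_collection(collection, ranking$locus_id[seq_len(k)]))
  names(members) <- labels
  new_submatrix_series("cumulative", members,
                       list(cut_points = cut_points))
}

#' Non-overlapping block submatrices along the conservation ranking
#'
#' Splits the ranking into consecutive blocks of `block_size` loci (the
#' final block holds the remainder), so each member isolates one slice of
#' the rate spectrum with no contribution from slower loci. A 277-locus
#' ranking at block size 50 yields five 50-locus blocks and one 27-locus
#' block.
#'
#' @param collection An [orthogroup_collection()].
#' @param block_size Positive integer.
#' @param ranking Optional precomputed [rank_by_conservation()] result.
#' @param labels Member labels; the default continues the lettering of a
#'   four-member cumulative series (`E`, `F`, ...) when it fits.
#' @return A `submatrix_series` with `series_id = "block"`.
#' @export
block_submatrices <- function(collection, block_size,
                              ranking = rank_by_conservation(collection),
                              labels = NULL) {
  n <- length(collection$loci)
  block_size <- as.integer(block_size)
  if (length(block_size) != 1 || is.na(block_size) || block_size < 1)
    stop("block_size must be a positive integer")
  starts <- seq(1L, n, by = block_size)
  ends <- pmin(starts + block_size - 1L, n)
  nb <- length(starts)
  if (is.null(labels)) {
    labels <- if (nb + 4L <= 26L) LETTERS[4L + seq_len(nb)]
              else sprintf("block_%02d", seq_len(nb))
  }
  members <- mapply(function(s, e)
    subset_collection(collection, ranking$locus_id[s:e]),
    starts, ends, SIMPLIFY = FALSE)
  names(members) <- labels
  new_submatrix_series("block", members, list(block_size = block_size))
}

#' Sizes of the members of a submatrix series
#' @param series A `submatrix_series`.
#' @return Named integer vector of member locus counts.
#' @export
series_sizes <- function(series) {
  vapply(series$members, function(m) length(m$loci), integer(1))
}

#' Write a conservation ranking as TSV
#' @param ranking A [rank_by_conservation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
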