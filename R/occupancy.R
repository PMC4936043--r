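#' Gene occupancy of a locus
#'
#' Number of taxa whose sequence in this locus contains at least one
#' non-gap character. A taxon whose row is all `'-'` is treated as
#' unsampled for this gene; a row of only `'X'` counts as present
#' (sequenced but ambiguous).
#'
#' @param locus A [locus_alignment()].
#' @return Integer count of sampled taxa.
#' @export
taxon_occupancy <- function(locus) {
  stopifnot(inherits(locus, "locus_alignment"))
  sum(vapply(locus$sequences, function(s) grepl("[^-]", s), logical(1)))
}

#' Filter orthogroups by minimum taxon occupancy
#'
#' Retains exactly the loci sampled for at least `min_taxa` taxa, in input
#' order. On a 49-taxon universe, thresholds 24 / 36 / 44 reproduce the
#' 50% / 75% / 90% occupancy tiers commonly used for supermatrix
#' construction. The taxon universe is preserved.
#'
#' @param collection An [orthogroup_collection()].
#' @param min_taxa Integer in `[1, |taxon_universe|]`.
#' @return A filtered [orthogroup_collection()].
#' @export
filter_by_min_taxa <- function(collection, min_taxa) {
  stopifnot(inherits(collection, "orthogroup_collection"))
  n_univ <- length(collection$taxon_universe)
  if (!is.numeric(min_taxa) || length(min_taxa) != 1 ||
      min_taxa < 1 || min_taxa > n_univ)
    stop(sprintf("min_taxa must be in [1, %d]", n_univ))
  occ <- vapply(collection$loci, taxon_occupancy, integer(1))
  keep <- names(occ)[occ >= min_taxa]
  if (length(keep) == 0)
    stop(sprintf("no locus has occupancy >= %d", min_taxa))
  subset_collection(collection, keep)
}

# low-level supermatrix constructor (already-concatenated rows)
new_supermatrix <- function(sequences, partitions) {
  obj <- structure(
    list(taxa = names(sequences),
         sequences = sequences,
         n_columns = nchar(sequences[[1]]),
         partitions = partitions),
    class = "supermatrix")
  if (any(nchar(sequences) != obj$n_columns))
    stop("supermatrix rows have unequal length")
  check_partition_tiling(partitions, obj$n_columns)
  obj
}

#' Concatenate a collection into a supermatrix
#'
#' Every taxon of the universe receives a row; a taxon absent from a locus
#' is filled with `'-'` across that locus's full column range. The
#' partition table records each locus's range in input order, in 0-based
#' half-open coordinates.
#'
#' @param collection An [orthogroup_collection()].
#' @return A `supermatrix` with fields `taxa`, `sequences`, `n_columns`
#'   and `partitions` (`locus_id`, `start`, `end`).
#' @export
concatenate_loci <- function(collection) {
  stopifnot(inherits(collection, "orthogroup_collection"))
  taxa <- collection$taxon_universe
  lens <- vapply(collection$loci, `[[`, 0, "n_columns")
  ends <- cumsum(lens)
  parts <- data.frame(locus_id = names(collection$loci),
                      start = as.integer(ends - lens),
                      end = as.integer(ends),
                      stringsAsFactors = FALSE)
  rownames(parts) <- NULL
  pieces <- lapply(collection$loci, function(l) {
    gaprow <- strrep(.GAP, l$n_columns)
    out <- l$sequences[match(taxa, names(l$sequences))]
    out[is.na(out)] <- gaprow
    out
  })
  seqs <- do.call(paste0, pieces)
  names(seqs) <- taxa
  new_supermatrix(seqs, parts)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$n_columns, nrow(x$partitions)))
  invisible(x)
}

#' Extract one locus back out of a supermatrix
#'
#' Slices the column range of `locus_id` from the concatenation. With
#' `drop_all_gap = TRUE` (default), taxa that are entirely gap in this
#' range — i.e. were absent from the original locus — are removed, so the
#' result reproduces the input locus exactly.
#'
#' @param matrix A [supermatrix][concatenate_loci()].
#' @param locus_id Locus identifier present in the partition table.
#' @param drop_all_gap Drop taxa whose slice is all `'-'`.
#' @return A [locus_alignment()].
#' @export
extract_locus <- function(matrix, locus_id, drop_all_gap = TRUE) {
  stopifnot(inherits(matrix, "supermatrix"))
  i <- match(locus_id, matrix$partitions$locus_id)
  if (is.na(i)) stop(sprintf("unknown locus_id: '%s'", locus_id))
  start <- matrix$partitions$start[i]
  end <- matrix$partitions$end[i]
  sl <- substr(matrix$sequences, start + 1L, end)
  names(sl) <- matrix$taxa
  if (drop_all_gap) sl <- sl[grepl("[^-]", sl)]
  locus_alignment(sl, locus_id = locus_id)
}

#' Occupancy table of a collection
#'
#' Presence/absence of each (locus, taxon) pair, with taxa (columns)
#' ordered by decreasing gene count and loci (rows) by decreasing
#' occupancy, so maximum occupancy sits towards the top left of the
#' matrix — the usual occupancy-plot convention.
#'
#' @param collection An [orthogroup_collection()].
#' @return An `occupancy_report`: list with `presence` (loci x taxa 0/1
#'   matrix), `per_locus` (named occupancy counts) and `per_taxon` (named
#'   gene counts), all in sorted order.
#' @export
occupancy_table <- function(collection) {
  stopifnot(inherits(collection, "orthogroup_collection"))
  taxa <- collection$taxon_universe
  pres <- t(vapply(collection$loci, function(l) {
    s <- l$sequences[match(taxa, names(l$sequences))]
    !is.na(s) & grepl("[^-]", s)
  }, logical(length(taxa))))
  dimnames(pres) <- list(locus_ids(collection), taxa)
  per_locus <- rowSums(pres)
  per_taxon <- colSums(pres)
  ro <- order(-per_locus, rownames(pres), method = "radix")
  co <- order(-per_taxon, colnames(pres), method = "radix")
  pres <- pres[ro, co, drop = FALSE]
  structure(list(presence = pres * 1L,
                 per_locus = per_locus[ro],
                 per_taxon = per_taxon[co]),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("<occupancy_report> %d loci x %d taxa, mean occupancy %.3f\n",
              nrow(x$presence), ncol(x$presence), mean(x$presence)))
  invisible(x)
}

#' Write an occupancy report as TSV
#'
#' @param report An [occupancy_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_report <- function(report, path) {
  df <- data.frame(locus_id = rownames(report$presence),
                   occupancy = as.integer(report$per_locus),
                   report$presence, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
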