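#' A collection of orthogroup alignments over a shared taxon universe
#'
#' The unit consumed by matrix construction: an ordered list of
#' [locus_alignment()] objects plus the taxon universe they live in. The
#' universe may be a superset of the taxa actually present — subsetting
#' operations ([filter_by_min_taxa()], [cumulative_submatrices()],
#' [block_submatrices()]) deliberately preserve the parent universe so that
#' supermatrices and tree sets derived from different subsets share one leaf
#' set.
#'
#' @param loci List of [locus_alignment()] objects with unique `locus_id`s.
#' @param taxon_universe Optional character vector of taxon labels; defaults
#'   to the union of taxa over all loci, in order of first appearance.
#' @return An object of class `orthogroup_collection` with fields `loci`
#'   (named by locus id) and `taxon_universe`.
#' @export
orthogroup_collection <- function(loci, taxon_universe = NULL) {
  if (length(loci) == 0) stop("collection must contain at least one locus")
  ok <- vapply(loci, inherits, logical(1), "locus_alignment")
  if (!all(ok)) stop("all elements of 'loci' must be locus_alignment objects")
  ids <- vapply(loci, `[[`, "", "locus_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate locus_id: '%s'", ids[duplicated(ids)][1]))
  names(loci) <- ids
  seen <- unique(unlist(lapply(loci, function(l) names(l$sequences)),
                        use.names = FALSE))
  if (is.null(taxon_universe)) {
    taxon_universe <- seen
  } else {
    miss <- setdiff(seen, taxon_universe)
    if (length(miss) > 0)
      stop(sprintf("taxon '%s' appears in a locus but not in taxon_universe",
                   miss[1]))
  }
  structure(list(loci = loci, taxon_universe = taxon_universe),
            class = "orthogroup_collection")
}

#' @export
print.orthogroup_collection <- function(x, ...) {
  cat(sprintf("<orthogroup_collection> %d loci, %d taxa, %d total columns\n",
              length(x$loci), length(x$taxon_universe),
              sum(vapply(x$loci, `[[`, 0, "n_columns"))))
  invisible(x)
}

#' Locus identifiers of a collection
#' @param collection An [orthogroup_collection()].
#' @return Character vector of locus ids, in collection order.
#' @export
locus_ids <- function(collection) names(collection$loci)

# subset by locus id, preserving the parent taxon universe and the
# requested order
subset_collection <- function(collection, ids) {
  miss <- setdiff(ids, locus_ids(collection))
  if (length(miss) > 0)
    stop(sprintf("unknown locus_id: '%s'", miss[1]))
  orthogroup_collection(collection$loci[ids],
                        taxon_universe = collection$taxon_universe)
}

#' Write a collection as one FASTA file per locus
#'
#' @param collection An [orthogroup_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_orthogroup_dir <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in collection$loci)
    write_fasta_alignment(l, file.path(dir, paste0(l$locus_id, ".fasta")))
  invisible(dir)
}
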