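#' Single-locus amino-acid alignment
#'
#' Container for one orthogroup's aligned sequences. Residue strings are
#' upper-cased and `'?'` is normalized to the single missing symbol `'-'`;
#' `'X'` is kept distinct as a present-but-ambiguous residue. All sequences
#' must have identical length and use only the 20 canonical amino-acid
#' letters plus `'-'` and `'X'`.
#'
#' @param sequences Named character vector: taxon label -> aligned residue
#'   string. Names must be unique, non-empty and contain no whitespace.
#' @param locus_id Identifier for the locus (defaults to `"locus"`; file
#'   readers use the file stem).
#' @return An object of class `locus_alignment` with fields `locus_id`,
#'   `sequences` and `n_columns`.
#' @seealso [read_fasta_alignment()], [orthogroup_collection()]
#' @export
#' @examples
#' locus_alignment(c(t1 = "AC-D", t2 = "acad"), "g1")
locus_alignment <- function(sequences, locus_id = "locus") {
  if (!is.character(sequences) || length(sequences) == 0)
    stop("'sequences' must be a non-empty character vector")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("'sequences' must be named by taxon label")
  seqs <- toupper(sequences)
  seqs <- gsub("?", .GAP, seqs, fixed = TRUE)
  obj <- structure(
    list(locus_id = as.character(locus_id)[1],
         sequences = seqs,
         n_columns = nchar(seqs[[1]])),
    class = "locus_alignment")
  validate_locus_alignment(obj)
}

validate_locus_alignment <- function(x) {
  taxa <- names(x$sequences)
  if (anyDuplicated(taxa))
    stop(sprintf("duplicate taxon label in locus '%s': '%s'",
                 x$locus_id, taxa[duplicated(taxa)][1]))
  if (any(grepl("[[:space:]]", taxa)))
    stop(sprintf("taxon label with whitespace in locus '%s': '%s'",
                 x$locus_id, taxa[grepl("[[:space:]]", taxa)][1]))
  widths <- nchar(x$sequences)
  if (any(widths != x$n_columns)) {
    bad <- taxa[widths != x$n_columns][1]
    stop(sprintf(
      "ragged alignment in locus '%s': taxon '%s' has %d columns, expected %d",
      x$locus_id, bad, nchar(x$sequences[[bad]]), x$n_columns))
  }
  if (x$n_columns < 1)
    stop(sprintf("locus '%s' has zero columns", x$locus_id))
  ok <- paste0("^[", paste(c(aa_states(), .AMBIG), collapse = ""), "-]+$")
  bad <- !grepl(ok, x$sequences)
  if (any(bad)) {
    tx <- taxa[bad][1]
    ch <- setdiff(strsplit(x$sequences[[tx]], "")[[1]], .valid_chars())[1]
    stop(sprintf("invalid residue '%s' for taxon '%s' in locus '%s'",
                 ch, tx, x$locus_id))
  }
  x
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d taxa x %d columns\n",
              x$locus_id, length(x$sequences), x$n_columns))
  invisible(x)
}

#' Taxon labels of an alignment object
#'
#' @param x A `locus_alignment`, `supermatrix` or `orthogroup_collection`.
#' @return Character vector of taxon labels.
#' @export
taxa_of <- function(x) {
  if (inherits(x, "orthogroup_collection")) return(x$taxon_universe)
  names(x$sequences)
}
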