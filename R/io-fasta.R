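#' Read one aligned FASTA file as a locus alignment
#'
#' Reads an aligned amino-acid FASTA file, upper-casing residues and
#' normalizing `'?'` to `'-'`. Sequences of unequal length are rejected with
#' an error naming the offending taxon.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A [locus_alignment()].
#' @export
read_fasta_alignment <- function(path,
                                 locus_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0)
    stop(sprintf("malformed FASTA '%s': no records", path))
  if (!startsWith(trimws(first[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA '%s': line %d does not start a record",
                 path, nonblank[1]))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e))))
  if (length(set) == 0)
    stop(sprintf("malformed FASTA '%s': no records", path))
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1)
  locus_alignment(seqs, locus_id = locus_id)
}

#' Write an alignment or supermatrix as FASTA
#'
#' @param x A `locus_alignment` or `supermatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path) {
  seqs <- x$sequences
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read a directory of per-orthogroup FASTA alignments
#'
#' Each file becomes one locus, with the file stem as `locus_id`. The taxon
#' universe of the returned collection is the union of all taxa, in order of
#' first appearance.
#'
#' @param dir Directory containing FASTA files.
#' @param pattern Regular expression selecting alignment files.
#' @return An [orthogroup_collection()].
#' @export
read_orthogroup_dir <- function(dir, pattern = "\\.(fa|faa|fas|fasta)$") {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no FASTA files matching '%s' in %s", pattern, dir))
  loci <- lapply(files, read_fasta_alignment)
  orthogroup_collection(loci)
}
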