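#' Write a supermatrix in relaxed PHYLIP format
#'
#' Relaxed (sequential, one line per taxon) PHYLIP: a header line
#' `"ntaxa ncolumns"` followed by `"label sequence"` lines. Taxon labels
#' containing whitespace are rejected so the format stays unambiguous.
#'
#' @param matrix A non-empty [supermatrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  if (length(matrix$taxa) == 0 || matrix$n_columns == 0)
    stop("cannot write an empty supermatrix")
  if (any(grepl("[[:space:]]", matrix$taxa)))
    stop("taxon labels must not contain whitespace for PHYLIP output")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(matrix$taxa), matrix$n_columns), con)
  writeLines(paste(matrix$taxa, matrix$sequences[matrix$taxa]), con)
  invisible(path)
}

#' Read a relaxed PHYLIP supermatrix
#'
#' Inverse of [write_phylip()]. The partition table is not part of the
#' PHYLIP format, so the result carries a single partition spanning all
#' columns.
#'
#' @param path Path to a relaxed PHYLIP file.
#' @return A [supermatrix] with one partition named `"all"`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop(sprintf("malformed PHYLIP '%s'", path))
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop(sprintf("malformed PHYLIP header in '%s'", path))
  body <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  if (length(body) != hdr[1])
    stop(sprintf("PHYLIP '%s': expected %d taxa, found %d",
                 path, hdr[1], length(body)))
  seqs <- vapply(body, function(x) paste(x[-1], collapse = ""), "")
  names(seqs) <- vapply(body, `[`, "", 1)
  if (any(nchar(seqs) != hdr[2]))
    stop(sprintf("PHYLIP '%s': sequence length disagrees with header", path))
  new_supermatrix(seqs, data.frame(locus_id = "all", start = 0L,
                                   end = hdr[2], stringsAsFactors = FALSE))
}

#' Write a RAxML-style partition file
#'
#' One line per locus, `"MODEL, locus_id = start-end"`, with 1-based
#' inclusive column ranges in concatenation order (internal coordinates are
#' 0-based half-open). Ranges must tile the matrix exactly.
#'
#' @param matrix A [supermatrix] with a non-empty partition table.
#' @param model_tag Substitution-model label written on every line, e.g.
#'   `"WAG"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(matrix, model_tag, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  parts <- matrix$partitions
  if (is.null(parts) || nrow(parts) == 0)
    stop("supermatrix has an empty partition table")
  check_partition_tiling(parts, matrix$n_columns)
  lines <- sprintf("%s, %s = %d-%d", model_tag, parts$locus_id,
                   parts$start + 1L, parts$end)
  writeLines(lines, path)
  invisible(path)
}

# internal-consistency check: partitions must tile [0, n_columns) exactly
check_partition_tiling <- function(parts, n_columns) {
  if (parts$start[1] != 0L)
    stop("internal consistency: first partition does not start at column 0")
  if (nrow(parts) > 1 && any(parts$start[-1] != parts$end[-nrow(parts)]))
    stop("internal consistency: partition ranges overlap or leave gaps")
  if (parts$end[nrow(parts)] != n_columns)
    stop("internal consistency: partitions do not cover all columns")
  if (any(parts$end <= parts$start))
    stop("internal consistency: empty partition range")
  invisible(TRUE)
}
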