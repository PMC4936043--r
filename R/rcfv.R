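#' Per-taxon amino-acid state frequencies
#'
#' Empirical frequencies of the 20 canonical amino acids for each taxon,
#' computed over that taxon's usable residues only — gaps and `'X'` are
#' excluded, so missing data register no compositional signal. Taxa with
#' zero usable residues are flagged and excluded from the frequency table
#' (with a warning), never silently averaged in.
#'
#' @param matrix A [supermatrix][concatenate_loci()] or
#'   [locus_alignment()].
#' @return A `state_frequency_table`: list with `frequencies` (taxa x 20
#'   matrix, rows summing to 1), `residue_counts` and `flagged_taxa`.
#' @export
taxon_state_frequencies <- function(matrix) {
  if (!inherits(matrix, "supermatrix") && !inherits(matrix, "locus_alignment"))
    stop("'matrix' must be a supermatrix or locus_alignment")
  codes <- seq_code_matrix(matrix$sequences)
  counts <- vapply(seq_len(20L), function(s) rowSums(codes == s, na.rm = TRUE),
                   numeric(nrow(codes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  dimnames(counts) <- list(rownames(codes), aa_states())
  usable <- rowSums(counts)
  flagged <- rownames(counts)[usable == 0]
  if (length(flagged) > 0)
    warning(sprintf("taxa with zero usable residues excluded: %s",
                    paste(flagged, collapse = ", ")))
  keep <- usable > 0
  if (sum(keep) < 2)
    stop("fewer than 2 taxa with usable residues")
  freq <- counts[keep, , drop = FALSE] / usable[keep]
  structure(list(frequencies = freq,
                 residue_counts = usable[keep],
                 flagged_taxa = flagged),
            class = "state_frequency_table")
}

#' Relative composition frequency variability (RCFV)
#'
#' Compositional-heterogeneity screen for a supermatrix. With
#' \eqn{f_{s,t}} the frequency of state \eqn{s} in taxon \eqn{t},
#' \eqn{\bar f_s} the across-taxon mean, and \eqn{n} the number of taxa,
#' each (state, taxon) pair contributes \eqn{|f_{s,t} - \bar f_s| / n}.
#' Summing over states gives the per-taxon tRCFV, over taxa the per-state
#' csRCFV, and over both the total; the two groupings are the same double
#' sum and always agree. Values near zero indicate compositional
#' homogeneity; a compositionally deviant taxon stands out by its tRCFV.
#'
#' @param matrix A [supermatrix][concatenate_loci()] or
#'   [locus_alignment()].
#' @return An `rcfv_report`: list with `per_taxon` (sorted by descending
#'   tRCFV), `per_state`, `total`, `n_taxa` and `flagged_taxa`.
#' @export
#' @examples
#' loc <- locus_alignment(c(t1 = "AAAA", t2 = "GGGG"))
#' rcfv(loc)$total  # 1.0
rcfv <- function(matrix) {
  sft <- taxon_state_frequencies(matrix)
  freq <- sft$frequencies
  n <- nrow(freq)
  fbar <- colMeans(freq)
  dev <- abs(sweep(freq, 2, fbar)) / n
  per_taxon <- rowSums(dev)
  per_taxon <- per_taxon[order(-per_taxon, names(per_taxon),
                               method = "radix")]
  structure(list(per_taxon = per_taxon,
                 per_state = colSums(dev),
                 total = sum(dev),
                 n_taxa = n,
                 flagged_taxa = sft$flagged_taxa),
            class = "rcfv_report")
}

#' @export
print.rcfv_report <- function(x, ...) {
  cat(sprintf("<rcfv_report> %d taxa, total RCFV = %.6g\n", x$n_taxa, x$total))
  cat(sprintf("  tRCFV range: %.6g .. %.6g (max: %s)\n",
              min(x$per_taxon), max(x$per_taxon), names(x$per_taxon)[1]))
  if (length(x$flagged_taxa) > 0)
    cat("  flagged (no usable residues):",
        paste(x$flagged_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Write an RCFV report as TSV
#'
#' Emits both groupings — per taxon and per amino acid — plus the total,
#' in one long-format table with columns `kind`, `label`, `rcfv`.
#'
#' @param report An [rcfv()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rcfv_report <- function(report, path) {
  df <- rbind(
    data.frame(kind = "taxon", label = names(report$per_taxon),
               rcfv = unname(report$per_taxon)),
    data.frame(kind = "state", label = names(report$per_state),
               rcfv = unname(report$per_state)),
    data.frame(kind = "total", label = "total", rcfv = report$total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
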