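#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes, in the fixed order used
#' throughout the package for frequency vectors, simulation stationary
#' distributions and RCFV reports.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_states()
aa_states <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.GAP <- "-"
.AMBIG <- "X"

.valid_chars <- function() c(aa_states(), .GAP, .AMBIG)

# taxa x columns character matrix from a named vector of residue strings
seq_char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# integer codes 1..20 for canonical residues, NA for gap and 'X';
# this is the "usable residue" view shared by the conservation, RCFV and
# distance computations
seq_code_matrix <- function(seqs) {
  m <- seq_char_matrix(seqs)
  codes <- match(m, aa_states())
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}
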