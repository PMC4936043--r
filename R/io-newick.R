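#' Parse a newick string into a tree
#'
#' Thin, validating wrapper around [ape::read.tree()]: checks parenthesis
#' balance up front, rejects duplicate leaf labels, and accepts optional
#' branch lengths and internal support labels.
#'
#' @param text A single newick string (terminated by `;`).
#' @return An [ape::phylo] tree.
#' @export
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2)95:0.05,C:0.3,D:0.4);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  no <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nc <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (no != nc)
    stop(sprintf("newick parse error: %d '(' vs %d ')'", no, nc))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop(sprintf("newick parse error: %s",
                                                  conditionMessage(e))))
  if (is.null(tr)) stop("newick parse error: not a valid tree")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup) > 0)
    stop(sprintf("duplicate leaf label: '%s'", dup[1]))
  tr
}

#' Serialize a tree to a newick string
#'
#' @param tree An [ape::phylo] tree.
#' @return A newick string with trailing `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10)
}

#' Read a file of newick trees (one per line)
#'
#' @param path Path to a newick file, e.g. a set of bootstrap trees.
#' @return A `multiPhylo` list of trees.
#' @export
read_tree_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  trs <- ape::read.tree(path)
  if (inherits(trs, "phylo")) trs <- structure(list(trs), class = "multiPhylo")
  trs
}

#' Write a set of trees to a newick file (one per line)
#'
#' @param trees A `multiPhylo` or list of [ape::phylo] trees.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path) {
  writeLines(vapply(trees, write_newick, ""), path)
  invisible(path)
}
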