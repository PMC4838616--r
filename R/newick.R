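# Newick I/O: thin wrappers over ape, kept as the single exit/entry point
# so bootstrap labels and branch lengths round-trip.

#' Write a tree to a Newick file
#'
#' Branch lengths are written in full precision; integer bootstrap supports
#' (node labels) appear after the closing parenthesis of their clade.
#'
#' @param tree a `phylo` object (optionally with `node.label`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (nrow(tree$edge) != length(tree$tip.label) + tree$Nnode - 1L)
    stop("tree is not a connected acyclic graph")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' @param path Newick file path.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
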