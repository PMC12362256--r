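#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validation UniFrac needs:
#' unique leaf labels, finite nonnegative branch lengths. Missing branch
#' lengths default to 0. Unrooted input is accepted as-is and treated as
#' rooted at its basal (possibly trifurcating) node, deterministically; no
#' midpoint re-rooting is performed, and UniFrac values are therefore
#' root-dependent in the usual way.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort(sprintf("Newick parse error in '%s'", path))
  validate_phylo(tree)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylogenetic tree")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort("branch lengths must be finite and >= 0")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf label: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  tree
}
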