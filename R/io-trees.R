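# Newick IO, delegated to ape.  Trees are ape "phylo" objects throughout
# the package; bootstrap supports live in node.label (the Newick
# internal-node-label convention).

#' Serialize a tree to a Newick string
#'
#' Branch lengths are written with 6 decimals and support values (if any)
#' as internal node labels, so that \code{read_newick(write_newick(x))}
#' reproduces labels, branch lengths and supports.
#'
#' @param tree An ape \code{phylo} object with unique leaf labels.
#' @return Newick string (single element, with trailing \code{";"}).
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree)
}

#' Parse a Newick string
#'
#' @param string Newick string (must end in \code{";"}).
#' @return An ape \code{phylo} object; internal node labels (e.g. bootstrap
#'   supports) are kept in \code{node.label}.
#' @export
read_newick <- function(string) {
  if (length(string) != 1L || !nzchar(string)) stop("newick parse error: empty input")
  n_open <- lengths(regmatches(string, gregexpr("\\(", string)))
  n_close <- lengths(regmatches(string, gregexpr("\\)", string)))
  if (n_open != n_close) stop("newick parse error: unbalanced parentheses")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = string)),
    error = function(e) NULL
  )
  if (is.null(tree)) stop("newick parse error")
  tree
}
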