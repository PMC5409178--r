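## Small helpers for rooted trees carrying a flagged post-duplication clade.
## Convention: the clade is marked by a node label (default "DUP") on its
## most recent common ancestor; the clade comprises that node, all its
## descendants, and the stem branch leading into it (the duplication occurs
## along the stem, so everything from the stem down is post-duplication).

AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Locate a flagged internal node by label
#'
#' @param tree an \code{ape::phylo} with node labels.
#' @param flag node label to find (default \code{"DUP"}).
#' @return Integer node number, or \code{NA} if not present.
#' @export
flaggedNode <- function(tree, flag = "DUP") {
  if (is.null(tree$node.label)) return(NA_integer_)
  hit <- which(tree$node.label == flag)
  if (!length(hit)) return(NA_integer_)
  if (length(hit) > 1) stop("multiple nodes labelled ", flag)
  length(tree$tip.label) + hit
}

## All node numbers in the subtree rooted at `node` (node included).
subtreeNodes <- function(tree, node) {
  nodes <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% nodes, 2]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  nodes
}

#' Tip labels of a flagged clade
#'
#' @inheritParams flaggedNode
#' @return Character vector of tip labels inside the clade.
#' @export
cladeTipLabels <- function(tree, flag = "DUP") {
  node <- flaggedNode(tree, flag)
  if (is.na(node)) stop("no node labelled ", flag, " in tree")
  nodes <- subtreeNodes(tree, node)
  tree$tip.label[nodes[nodes <= length(tree$tip.label)]]
}

## Edge indices (rows of tree$edge) belonging to the flagged clade, stem
## branch included. With `node = NA` returns integer(0).
cladeEdgeIndices <- function(tree, node) {
  if (is.na(node)) return(integer(0))
  nodes <- subtreeNodes(tree, node)
  which(tree$edge[, 2] %in% nodes)
}
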