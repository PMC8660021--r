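#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates tip-name
#' uniqueness, requires a rooted tree, and auto-assigns labels
#' (`Anc1`, `Anc2`, ...) to unlabeled internal nodes so that ancestral
#' nodes can be addressed by name downstream.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] object with unique tip labels, node labels and
#'   nonnegative branch lengths.
#' @export
read_newick <- function(path) {
  tree <- if (file.exists(path)) {
    ape::read.tree(path)
  } else {
    .stop_if(!grepl(";", path, fixed = TRUE),
             "Newick file not found (and not a Newick string): ", path)
    suppressWarnings(ape::read.tree(text = path))
  }
  .stop_if(is.null(tree), "could not parse Newick input")
  prepare_tree(tree)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
prepare_tree <- function(tree) {
  .stop_if(!inherits(tree, "phylo"), "`tree` must be an ape phylo object")
  .stop_if(anyDuplicated(tree$tip.label) > 0L,
           "duplicate tip name: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  # basal polytomies (e.g. star trees) are allowed: any ape phylo has a
  # unique root node, which the likelihood weights with the stationary
  # frequencies; a trifurcating root is treated as a rooted polytomy
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  .stop_if(any(tree$edge.length < 0), "negative branch length")
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  blank <- is.na(tree$node.label) | tree$node.label == ""
  tree$node.label[blank] <- paste0("Anc", which(blank))
  .stop_if(anyDuplicated(c(tree$tip.label, tree$node.label)) > 0L,
           "node labels must be unique and distinct from tip names")
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Precomputed traversal structure shared by the likelihood machinery.
# Nodes are ape indices: tips 1..ntip, root ntip+1, internals onward.
.tree_struct <- function(tree) {
  tree <- prepare_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- character(nnode)
  labels[seq_len(ntip)] <- tree$tip.label
  labels[(ntip + 1L):nnode] <- tree$node.label
  list(
    tree = tree,
    edge = po$edge,                  # postorder: children before parents
    edge_length = po$edge.length,
    ntip = ntip,
    nnode = nnode,
    root = ntip + 1L,
    labels = labels,
    children = split(seq_len(nrow(po$edge)), po$edge[, 1L])  # edges by parent
  )
}
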