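#' Read and write rooted trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser that validate the tree
#' for use in ancestral reconstruction: a single root, unique tip labels,
#' and named internal nodes (unnamed nodes are auto-labelled `node<k>`).
#'
#' @param text A Newick string (terminated by `;`).
#' @return An `ape::phylo` tree (rooted, with `node.label` set).
#' @examples
#' tr <- parse_newick("(A,(B,C)in1)root;")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(length(text) == 1, is.character(text))
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("malformed Newick: unbalanced ')' at character ", k, call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param path Path to a Newick file.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname parse_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  n_int <- tree$Nnode
  if (is.null(tree$node.label) || length(tree$node.label) != n_int) {
    tree$node.label <- paste0("node", seq_len(n_int) + ape::Ntip(tree))
  }
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- paste0("node", which(blank) + ape::Ntip(tree))
  if (anyDuplicated(c(tree$tip.label, tree$node.label))) {
    stop("node labels clash with tip labels", call. = FALSE)
  }
  tree
}

node_names <- function(tree) c(tree$tip.label, tree$node.label)

root_index <- function(tree) ape::Ntip(tree) + 1L

# children of each node as a list indexed by node number
children_list <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

postorder_nodes <- function(tree) {
  # parents after children; root appended last
  po <- ape::reorder.phylo(tree, "postorder")$edge
  unique(c(po[, 2], root_index(tree)))
}

preorder_nodes <- function(tree) {
  rev(postorder_nodes(tree))
}
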