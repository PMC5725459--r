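#' Read a rooted species tree from a newick file
#'
#' Wraps [ape::read.tree()] with stricter contracts: the file must contain a
#' single rooted tree with unique tip labels, unbalanced parentheses are
#' reported with their character position, and unnamed internal nodes are
#' given deterministic preorder names `A1, A2, ...` so downstream reports are
#' stable across runs.
#'
#' @param path Path to a newick file, or a literal newick string containing
#'   `(`/`;` (convenience for tests).
#' @return An [ape::phylo] tree with complete internal node labels.
#' @export
read_newick <- function(path) {
  txt <- if (grepl("[();]", path)) path else paste(readLines(path), collapse = "")
  txt <- trimws(txt)
  .check_parentheses(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick string")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, found ", length(tree))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  label_internal_nodes(tree)
}

.check_parentheses <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parenthesis at end of string (depth ", depth, ")")
  invisible(TRUE)
}

#' Name unnamed internal nodes in preorder
#'
#' Internal nodes without a label receive `A1, A2, ...` in preorder (root
#' first); existing labels are kept. Generated names are made unique against
#' existing ones.
#'
#' @param tree An [ape::phylo] tree.
#' @param prefix Label prefix, default `"A"`.
#' @return The tree with a complete `node.label` vector.
#' @export
label_internal_nodes <- function(tree, prefix = "A") {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  ord <- .internal_preorder(tree)          # node indices, root first
  taken <- c(tree$tip.label, lab[lab != ""])
  k <- 0L
  for (node in ord) {
    i <- node - ntip
    if (lab[i] == "") {
      repeat {
        k <- k + 1L
        cand <- paste0(prefix, k)
        if (!cand %in% taken) break
      }
      lab[i] <- cand
      taken <- c(taken, cand)
    }
  }
  tree$node.label <- lab
  tree
}

# Internal node indices in preorder (root first).
.internal_preorder <- function(tree) {
  ntip <- ape::Ntip(tree)
  ed <- stats::reorder(tree, "cladewise")$edge
  seen <- unique(c(ed[1, 1], as.vector(t(ed))))
  seen[seen > ntip]
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Names for every node index (tips then internals), and the branch table
# (one row per edge; a branch is identified by the name of its child node).
tree_node_names <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

tree_branches <- function(tree) {
  nm <- tree_node_names(tree)
  data.frame(parent = nm[tree$edge[, 1]],
             child = nm[tree$edge[, 2]],
             parent_idx = tree$edge[, 1],
             child_idx = tree$edge[, 2],
             branch_id = nm[tree$edge[, 2]],
             stringsAsFactors = FALSE)
}
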