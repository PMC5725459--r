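# Shared tree bookkeeping for the parsimony routines: binary rooted tree,
# complete internal labels, postorder edge list.
.parsimony_tree <- function(tree) {
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    tree <- label_internal_nodes(tree)
  }
  ntip <- ape::Ntip(tree)
  if (tree$Nnode != ntip - 1L) {
    stop("parsimony reconstruction requires a binary rooted tree")
  }
  po <- stats::reorder(tree, "postorder")$edge
  list(tree = tree, ntip = ntip, root = ntip + 1L,
       n_nodes = ntip + tree$Nnode,
       names = tree_node_names(tree),
       postorder = po)
}

#' Ancestral interaction states for many pairs by maximum parsimony
#'
#' Unit-cost parsimony (Fitch on binary characters, implemented as a
#' Sankoff dynamic program and vectorized across characters) on a binary
#' rooted species tree. Unknown tip states (`NA`) are unconstrained: the
#' score is the minimum number of state changes over all ancestral
#' labelings and all assignments of the unknown tips. Ambiguities in the
#' top-down pass are resolved by preferring the parent's resolved state
#' (`"deltran"`, the default) or the opposite (`"acctran"`, changes pulled
#' toward the root); both realize exactly the parsimony score. Root
#' ambiguity is resolved by the outgroup tip's state, and by absence (0)
#' when the outgroup is unknown.
#'
#' @param tree Binary rooted [ape::phylo] species tree whose tips cover the
#'   profiled species.
#' @param states Numeric matrix (characters x species) with values 0, 1 or
#'   `NA`; column names must name tree tips (tips without a column are
#'   treated as unknown). A row with no known state is an error.
#' @param outgroup Tip used to resolve root ambiguity (default `"mouse"`;
#'   ignored when absent from the tree).
#' @param resolve `"deltran"` or `"acctran"`.
#' @return List of class `parsimony_reconstruction`: `tree`, `node_states`
#'   (characters x all nodes, fully resolved 0/1), `score` (per-character
#'   parsimony score), `branches` (branch table, one row per edge,
#'   identified by the child node name).
#' @export
fitch_reconstruct_many <- function(tree, states, outgroup = "mouse",
                                   resolve = c("deltran", "acctran")) {
  resolve <- match.arg(resolve)
  pt <- .parsimony_tree(tree)
  tree <- pt$tree
  if (is.null(colnames(states))) stop("states matrix must have species column names")
  extra <- setdiff(colnames(states), tree$tip.label)
  if (length(extra)) {
    stop("states name species absent from tree: ", paste(extra, collapse = ", "))
  }
  n_char <- nrow(states)
  tip_states <- matrix(NA_real_, nrow = n_char, ncol = pt$ntip,
                       dimnames = list(rownames(states), tree$tip.label))
  tip_states[, colnames(states)] <- states
  if (any(rowSums(!is.na(tip_states)) == 0L)) {
    stop("character(s) with all tip states unknown: row ",
         which(rowSums(!is.na(tip_states)) == 0L)[1])
  }
  # bottom-up: minimal changes in the subtree given the node state
  INF <- Inf
  cost0 <- matrix(0, nrow = pt$n_nodes, ncol = n_char)
  cost1 <- matrix(0, nrow = pt$n_nodes, ncol = n_char)
  for (i in seq_len(pt$ntip)) {
    s <- tip_states[, i]
    cost0[i, ] <- ifelse(is.na(s) | s == 0, 0, INF)
    cost1[i, ] <- ifelse(is.na(s) | s == 1, 0, INF)
  }
  for (k in seq_len(nrow(pt$postorder))) {
    p <- pt$postorder[k, 1]; ch <- pt$postorder[k, 2]
    cost0[p, ] <- cost0[p, ] + pmin(cost0[ch, ], cost1[ch, ] + 1)
    cost1[p, ] <- cost1[p, ] + pmin(cost1[ch, ], cost0[ch, ] + 1)
  }
  score <- pmin(cost0[pt$root, ], cost1[pt$root, ])
  # root state; ties resolved by the outgroup, else by absence
  og_state <- rep(0, n_char)
  if (outgroup %in% tree$tip.label) {
    og <- tip_states[, outgroup]
    og_state <- ifelse(is.na(og), 0, og)
  }
  node_states <- matrix(NA_real_, nrow = n_char, ncol = pt$n_nodes,
                        dimnames = list(rownames(states), pt$names))
  root_state <- ifelse(cost1[pt$root, ] < cost0[pt$root, ], 1,
                       ifelse(cost0[pt$root, ] < cost1[pt$root, ], 0, og_state))
  node_states[, pt$root] <- root_state
  # top-down in preorder (reverse postorder)
  for (k in rev(seq_len(nrow(pt$postorder)))) {
    p <- pt$postorder[k, 1]; ch <- pt$postorder[k, 2]
    sp <- node_states[, p]
    cost_same <- ifelse(sp == 0, cost0[ch, ], cost1[ch, ])
    cost_diff <- ifelse(sp == 0, cost1[ch, ], cost0[ch, ]) + 1
    take_diff <- if (resolve == "deltran") cost_diff < cost_same
                 else cost_diff <= cost_same
    node_states[, ch] <- ifelse(take_diff, 1 - sp, sp)
  }
  structure(list(tree = tree, node_states = node_states, score = score,
                 branches = tree_branches(tree), resolve = resolve,
                 outgroup = outgroup),
            class = "parsimony_reconstruction")
}

#' Ancestral states of one interaction profile by maximum parsimony
#'
#' Single-character convenience wrapper around [fitch_reconstruct_many()].
#' Additionally reports the bottom-up state set of every node (the states
#' achieving the minimal subtree cost: `"0"`, `"1"` or `"0/1"`).
#'
#' @inheritParams fitch_reconstruct_many
#' @param states Named vector of tip states (0, 1, `NA` for unknown, or the
#'   strings `"present"`/`"absent"`/`"unknown"`).
#' @return List with `node_states` (named 0/1 vector over all nodes),
#'   `state_sets` (named character vector), `score` (parsimony score),
#'   `tree`.
#' @export
fitch_reconstruct <- function(tree, states, outgroup = "mouse",
                              resolve = c("deltran", "acctran")) {
  if (is.character(states)) {
    states <- setNames(c(present = 1, absent = 0,
                         unknown = NA_real_)[states], names(states))
  }
  m <- matrix(as.numeric(states), nrow = 1,
              dimnames = list("profile", names(states)))
  rec <- fitch_reconstruct_many(tree, m, outgroup = outgroup,
                                resolve = resolve)
  # per-node optimal-state sets from the DP costs
  pt <- .parsimony_tree(rec$tree)
  tip_states <- setNames(rep(NA_real_, pt$ntip), rec$tree$tip.label)
  tip_states[names(states)] <- as.numeric(states)
  cost0 <- ifelse(is.na(tip_states) | tip_states == 0, 0, Inf)
  cost1 <- ifelse(is.na(tip_states) | tip_states == 1, 0, Inf)
  cost0 <- c(cost0, rep(0, pt$n_nodes - pt$ntip))
  cost1 <- c(cost1, rep(0, pt$n_nodes - pt$ntip))
  for (k in seq_len(nrow(pt$postorder))) {
    p <- pt$postorder[k, 1]; ch <- pt$postorder[k, 2]
    cost0[p] <- cost0[p] + min(cost0[ch], cost1[ch] + 1)
    cost1[p] <- cost1[p] + min(cost1[ch], cost0[ch] + 1)
  }
  sets <- ifelse(cost0 < cost1, "0", ifelse(cost1 < cost0, "1", "0/1"))
  names(sets) <- pt$names
  list(node_states = setNames(rec$node_states[1, ], colnames(rec$node_states)),
       state_sets = sets,
       score = unname(rec$score),
       tree = rec$tree)
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("parsimony_reconstruction: %d characters on %d-tip ",
                     "tree (total score %d, resolve=%s)\n"),
              nrow(x$node_states), ape::Ntip(x$tree), sum(x$score), x$resolve))
  invisible(x)
}
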