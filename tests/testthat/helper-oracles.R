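# Independent oracles and small fixtures used across the suite.

species_tree <- function() {
  read_newick("(((dog,cat),(horse,(pig,cow))),mouse);")
}

# Minimum number of state changes over all ancestral labelings AND all
# assignments of unknown (NA) tips, by exhaustive enumeration.
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  ed <- tree$edge
  states <- tip_states[tree$tip.label]
  free <- c(which(is.na(states)), (ntip + 1):(ntip + nn))
  n_free <- length(free)
  combos <- as.matrix(expand.grid(rep(list(0:1), n_free)))
  full <- matrix(rep(c(states, rep(NA_real_, nn)), each = nrow(combos)),
                 nrow = nrow(combos))
  full[, free] <- combos
  changes <- rep(0L, nrow(combos))
  for (k in seq_len(nrow(ed))) {
    changes <- changes + (full[, ed[k, 1]] != full[, ed[k, 2]])
  }
  min(changes)
}

# Propagation fixed point by a dense linear solve (dangling columns
# redirected to the seed distribution, as in the iterative scheme).
dense_rwr_solve <- function(network, seeds, restart_probability,
                            weighted = TRUE) {
  A <- as.matrix(snpnetevo:::network_adjacency(network, weighted = weighted))
  n <- nrow(A)
  deg <- colSums(A)
  e <- setNames(numeric(n), network$nodes)
  e[seeds] <- 1 / length(seeds)
  W <- A
  for (j in seq_len(n)) {
    W[, j] <- if (deg[j] > 0) A[, j] / deg[j] else e
  }
  cc <- restart_probability
  drop(solve(diag(n) - (1 - cc) * W, cc * e))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# foreground draws (backgrounds up to ~12 genes).
enumerate_hyper_p <- function(N, K, n, k_obs) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # term genes are 1..K w.l.o.g.
  mean(hits >= k_obs)
}

# A small deterministic callset built in code.
toy_callset <- function(variants, geno, population) {
  snpnetevo:::make_callset(variants, geno, population)
}
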