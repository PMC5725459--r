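#' Simulate the evolution of protein interactions on a species tree
#'
#' Each protein pair's interaction evolves root-to-tips as a two-state
#' Markov process: along every branch an absent interaction appears with
#' probability `gain_rate` and a present one disappears with probability
#' `loss_rate`. A designated subset of pairs (`planted_fraction` of them,
#' recorded in the returned truth) uses `gain_rate * excess_factor`
#' (capped at 1) on the planted branch, so that with `excess_factor = 1`
#' the planted pairs are statistically exchangeable with the rest. The
#' observable output mirrors what the transfer stage consumes: an ortholog
#' map with 1-3 members per group and species (occasionally none, making
#' the pair unknown there), and per-species scored networks in which a
#' present pair has strictly more than half of its cross-group ortholog
#' pairs interacting at score >= 0.7, an absent pair at most half
#' (sometimes exactly half, plus sub-threshold noise edges).
#'
#' @param tree Binary rooted [ape::phylo] species tree (internal nodes are
#'   auto-named in preorder when unnamed).
#' @param n_pairs Number of focal protein pairs.
#' @param gain_rate,loss_rate Per-branch change probabilities in \[0, 1\].
#' @param planted_gain_branch Branch id (child node name) carrying the
#'   excess; must be a branch of the tree.
#' @param excess_factor Multiplier (>= 1) on `gain_rate` for planted pairs
#'   on the planted branch.
#' @param planted_fraction Fraction of pairs designated as planted
#'   (default 0.1).
#' @param root_present_prob Probability that a pair is present at the root.
#' @param unknown_rate Probability that a group is empty in a non-focal
#'   species (yielding unknown transferred states).
#' @param focal_species Name of the focal tip (default `"dog"`).
#' @param rng_seed Integer seed; identical seeds give identical histories.
#' @return List with `pairs` (data frame `pair_id`, `protein_a`,
#'   `protein_b`), `ortholog_map`, `networks` (named list of
#'   `scored_network`s per species), and `truth` (list: `planted_pairs`,
#'   `planted_gain_branch`, `excess_factor`, `states` — the true 0/1 state
#'   matrix pairs x all tree nodes).
#' @export
simulate_interaction_history <- function(tree, n_pairs = 2000,
                                         gain_rate = 0.05, loss_rate = 0.02,
                                         planted_gain_branch = "dog",
                                         excess_factor = 1,
                                         planted_fraction = 0.1,
                                         root_present_prob = 0.15,
                                         unknown_rate = 0.1,
                                         focal_species = "dog",
                                         rng_seed = 1L) {
  if (excess_factor < 1) stop("excess_factor must be at least 1")
  stopifnot(gain_rate >= 0, gain_rate <= 1, loss_rate >= 0, loss_rate <= 1)
  pt <- .parsimony_tree(tree)
  tree <- pt$tree
  branches <- tree_branches(tree)
  if (!planted_gain_branch %in% branches$branch_id) {
    stop("planted_gain_branch '", planted_gain_branch,
         "' is not a branch of the tree")
  }
  if (!focal_species %in% tree$tip.label) {
    stop("focal species '", focal_species, "' is not a tip of the tree")
  }
  set.seed(rng_seed)
  # distinct unordered protein pairs
  n_prot <- max(4L, ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2) + 2L)
  prots <- sprintf("D%04d", seq_len(n_prot))
  all_pairs <- t(combn(n_prot, 2))
  sel <- sample.int(nrow(all_pairs), n_pairs)
  pairs <- data.frame(pair_id = pair_key(prots[all_pairs[sel, 1]],
                                         prots[all_pairs[sel, 2]]),
                      protein_a = prots[all_pairs[sel, 1]],
                      protein_b = prots[all_pairs[sel, 2]],
                      stringsAsFactors = FALSE)
  planted <- sort(sample.int(n_pairs, round(planted_fraction * n_pairs)))
  # evolve states root -> tips (preorder over edges)
  states <- matrix(NA_real_, nrow = n_pairs, ncol = pt$n_nodes,
                   dimnames = list(pairs$pair_id, pt$names))
  states[, pt$root] <- rbinom(n_pairs, 1, root_present_prob)
  for (k in rev(seq_len(nrow(pt$postorder)))) {
    p <- pt$postorder[k, 1]; ch <- pt$postorder[k, 2]
    g <- rep(gain_rate, n_pairs)
    if (pt$names[ch] == planted_gain_branch) {
      g[planted] <- min(1, gain_rate * excess_factor)
    }
    ps <- states[, p]
    u <- runif(n_pairs)
    states[, ch] <- ifelse(ps == 0, as.numeric(u < g),
                           as.numeric(u >= loss_rate))
  }
  # ortholog groups: focal species 1:1, others 0-3 members per group
  species <- tree$tip.label
  map_rows <- list(data.frame(species = focal_species, protein_id = prots,
                              group_id = paste0("G", seq_len(n_prot)),
                              stringsAsFactors = FALSE))
  members <- list()  # members[[species]][[group index]]
  for (sp in setdiff(species, focal_species)) {
    sizes <- ifelse(runif(n_prot) < unknown_rate, 0L,
                    sample(1:3, n_prot, replace = TRUE))
    mem <- lapply(seq_len(n_prot), function(i) {
      if (sizes[i] == 0L) character(0)
      else sprintf("%s_%s_%d", sp, prots[i], seq_len(sizes[i]))
    })
    members[[sp]] <- mem
    keep <- sizes > 0L
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      species = sp,
      protein_id = unlist(mem[keep]),
      group_id = rep(paste0("G", seq_len(n_prot))[keep], sizes[keep]),
      stringsAsFactors = FALSE)
  }
  ortholog_map <- as_ortholog_map(do.call(rbind, map_rows))
  # species networks realizing the tip states through the majority rule
  networks <- list()
  for (sp in species) {
    tip_state <- states[, match(sp, pt$names)]
    ed_a <- character(0); ed_b <- character(0); ed_s <- numeric(0)
    if (sp == focal_species) {
      present <- tip_state == 1
      ed_a <- pairs$protein_a[present]
      ed_b <- pairs$protein_b[present]
      ed_s <- runif(sum(present), 0.70, 1)
    } else {
      for (i in seq_len(n_pairs)) {
        ia <- match(pairs$protein_a[i], prots)
        ib <- match(pairs$protein_b[i], prots)
        ma <- members[[sp]][[ia]]
        mb <- members[[sp]][[ib]]
        if (!length(ma) || !length(mb)) next
        cross_a <- rep(ma, times = length(mb))
        cross_b <- rep(mb, each = length(ma))
        n_cross <- length(cross_a)
        if (tip_state[i] == 1) {
          k_int <- floor(n_cross / 2) + 1L
        } else if (runif(1) < 0.3 && n_cross >= 2) {
          k_int <- floor(n_cross / 2)       # at-half boundary, still absent
        } else {
          k_int <- 0L
        }
        if (k_int > 0) {
          pick <- sample.int(n_cross, k_int)
          ed_a <- c(ed_a, cross_a[pick])
          ed_b <- c(ed_b, cross_b[pick])
          ed_s <- c(ed_s, runif(k_int, 0.70, 1))
        }
        # sub-threshold noise edges that the 0.7 cutoff must ignore
        if (tip_state[i] == 0 && runif(1) < 0.2) {
          pick <- sample.int(n_cross, 1)
          ed_a <- c(ed_a, cross_a[pick])
          ed_b <- c(ed_b, cross_b[pick])
          ed_s <- c(ed_s, runif(1, 0.1, 0.69))
        }
      }
    }
    networks[[sp]] <- suppressMessages(scored_network(
      data.frame(protein_a = ed_a, protein_b = ed_b, score = ed_s,
                 stringsAsFactors = FALSE)))
  }
  list(pairs = pairs,
       ortholog_map = ortholog_map,
       networks = networks,
       tree = tree,
       truth = list(planted_pairs = pairs$pair_id[planted],
                    planted_gain_branch = planted_gain_branch,
                    excess_factor = excess_factor,
                    states = states))
}
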