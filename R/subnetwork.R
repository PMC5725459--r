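#' Extract the high-confidence subnetwork induced by a protein set
#'
#' Keeps edges with both endpoints in the set and score at or above the
#' threshold (the bound is inclusive: a score of exactly 0.7 is retained
#' under the default).
#'
#' @param proteins Character vector of node ids.
#' @param network A [scored_network()].
#' @param min_score Minimum score, in \[0, 1\] (default 0.7).
#' @return A `scored_network` restricted to the induced high-scoring edges;
#'   its node set is the input protein set (so isolated members are kept).
#' @export
extract_subnetwork <- function(proteins, network, min_score = 0.7) {
  stopifnot(min_score >= 0, min_score <= 1)
  proteins <- unique(as.character(proteins))
  ed <- network$edges
  keep <- ed$protein_a %in% proteins & ed$protein_b %in% proteins &
    ed$score >= min_score
  scored_network(ed[keep, , drop = FALSE], nodes = proteins)
}

#' Edges absent from all excluded related species
#'
#' Restricts an edge set to interactions whose cross-species profile is
#' absent or unknown in every excluded species, and reports separately how
#' many kept edges are known-absent in all of them versus carrying at least
#' one unknown state.
#'
#' @param network A `scored_network` (the dog edge set under study).
#' @param profiles Character matrix of interaction profiles: rows named by
#'   [pair_key()] of the two proteins, columns by species, values
#'   `"present"`, `"absent"` or `"unknown"` (see
#'   [build_interaction_profiles()]).
#' @param excluded_species Species in which the interaction must not be
#'   present (default cat, horse, pig, cow).
#' @return List with `network` (kept edges), `n_known_absent`,
#'   `n_unknown_containing`, and `n_unprofiled` (edges without a profile
#'   row, which are dropped).
#' @export
lineage_specific_edges <- function(network, profiles,
                                   excluded_species = c("cat", "horse",
                                                        "pig", "cow")) {
  missing_sp <- setdiff(excluded_species, colnames(profiles))
  if (length(missing_sp)) {
    stop("profiles lack species: ", paste(missing_sp, collapse = ", "))
  }
  ed <- network$edges
  keys <- pair_key(ed$protein_a, ed$protein_b)
  idx <- match(keys, rownames(profiles))
  unprofiled <- is.na(idx)
  if (any(unprofiled)) {
    message(sum(unprofiled), " edge(s) without interaction profile dropped")
  }
  sub <- profiles[idx[!unprofiled], excluded_species, drop = FALSE]
  absentish <- sub != "present"
  keep_rows <- rowSums(absentish) == length(excluded_species)
  known_absent <- rowSums(sub == "absent") == length(excluded_species)
  kept_idx <- which(!unprofiled)[keep_rows]
  list(network = scored_network(ed[kept_idx, , drop = FALSE]),
       n_known_absent = sum(known_absent & keep_rows),
       n_unknown_containing = sum(keep_rows & !known_absent),
       n_unprofiled = sum(unprofiled))
}

#' Within- versus between-set interaction enrichment
#'
#' Tests whether interactions concentrate within two disjoint protein sets
#' rather than between them. Possible pairs are split into within-set
#' (A-A or B-B) and between-set (A-B); the one-sided p-value is the
#' hypergeometric upper tail for the number of interacting within-set pairs
#' given the total number of interacting pairs (equivalent to a one-sided
#' Fisher's exact test on the 2x2 table).
#'
#' @param set_a,set_b Disjoint, non-empty character vectors of protein ids.
#' @param network A `scored_network`; only edges with both endpoints inside
#'   `set_a` union `set_b` are considered.
#' @return List with `table` (2x2 matrix: within/between x
#'   interacting/non-interacting) and `p_value`.
#' @export
within_between_enrichment <- function(set_a, set_b, network) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a) || !length(set_b)) stop("both protein sets must be non-empty")
  if (length(intersect(set_a, set_b))) {
    stop("protein sets must be disjoint; shared: ",
         paste(head(intersect(set_a, set_b), 5), collapse = ", "))
  }
  na <- length(set_a); nb <- length(set_b)
  n_within <- choose(na, 2) + choose(nb, 2)
  n_between <- na * nb
  ed <- network$edges
  in_a1 <- ed$protein_a %in% set_a
  in_a2 <- ed$protein_a %in% set_b
  in_b1 <- ed$protein_b %in% set_a
  in_b2 <- ed$protein_b %in% set_b
  within_int <- sum((in_a1 & in_b1) | (in_a2 & in_b2))
  between_int <- sum((in_a1 & in_b2) | (in_a2 & in_b1))
  k_int <- within_int + between_int
  p <- stats::phyper(within_int - 1, n_within, n_between, k_int,
                     lower.tail = FALSE)
  tab <- matrix(c(within_int, n_within - within_int,
                  between_int, n_between - between_int),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("within", "between"),
                                c("interacting", "non_interacting")))
  list(table = tab, p_value = p)
}
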