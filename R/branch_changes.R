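#' Per-branch interaction gains and losses
#'
#' For every branch parent->child of the species tree, counts the pairs
#' whose reconstructed interaction appears (parent 0, child 1) or
#' disappears (parent 1, child 0), together with the denominators (pairs
#' without/with interaction at the parent) and the corresponding fractions.
#' A zero denominator yields an `NA` fraction, not 0. Summed over branches,
#' gains + losses of a pair equal its parsimony score.
#'
#' @param reconstruction A `parsimony_reconstruction` from
#'   [fitch_reconstruct_many()].
#' @return Data frame with one row per branch: `branch_id` (child node
#'   name), `parent`, `child`, `gains`, `losses`,
#'   `n_without_at_parent`, `n_with_at_parent`, `gain_fraction`,
#'   `loss_fraction`.
#' @export
branch_change_summary <- function(reconstruction) {
  st <- reconstruction$node_states
  br <- reconstruction$branches
  rows <- lapply(seq_len(nrow(br)), function(k) {
    ps <- st[, br$parent_idx[k]]
    cs <- st[, br$child_idx[k]]
    gains <- sum(ps == 0 & cs == 1)
    losses <- sum(ps == 1 & cs == 0)
    n0 <- sum(ps == 0); n1 <- sum(ps == 1)
    data.frame(branch_id = br$branch_id[k], parent = br$parent[k],
               child = br$child[k], gains = gains, losses = losses,
               n_without_at_parent = n0, n_with_at_parent = n1,
               gain_fraction = if (n0 > 0) gains / n0 else NA_real_,
               loss_fraction = if (n1 > 0) losses / n1 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$gains) + sum(out$losses) == sum(reconstruction$score))
  out
}

# Per-pair per-branch gain indicators and parent-absent indicators,
# the sufficient statistics for resampled gain fractions.
.branch_gain_indicators <- function(reconstruction) {
  st <- reconstruction$node_states
  br <- reconstruction$branches
  gains <- matrix(FALSE, nrow = nrow(st), ncol = nrow(br),
                  dimnames = list(rownames(st), br$branch_id))
  parent0 <- gains
  for (k in seq_len(nrow(br))) {
    ps <- st[, br$parent_idx[k]]
    cs <- st[, br$child_idx[k]]
    gains[, k] <- ps == 0 & cs == 1
    parent0[, k] <- ps == 0
  }
  list(gains = gains, parent0 = parent0)
}

#' Randomization test for per-branch gain fractions
#'
#' Compares the per-branch gain fraction of an observed pair set against a
#' null distribution built by drawing, `n` times, the same number of pairs
#' uniformly without replacement from the universe of profiled pairs and
#' recomputing the fraction with the same parsimony reconstruction. The
#' one-sided empirical p-value uses the add-one rule
#' `p = (1 + #{replicates >= observed}) / (n + 1)`, so it is bounded below
#' by `1/(n+1)` and is monotone non-increasing in the observed fraction.
#'
#' @param reconstruction A `parsimony_reconstruction` over the full
#'   universe of profiled pairs (row names are pair ids).
#' @param observed Character vector of pair ids (a subset of the universe)
#'   whose per-branch gain fractions are to be tested.
#' @param n Number of replicates (default 10000).
#' @param rng_seed Integer seed; the same seed gives an identical p vector.
#' @return Data frame with one row per branch: `branch_id`,
#'   `observed_gain_fraction`, `p_value` (`NA` when the observed
#'   denominator is zero).
#' @export
randomization_test <- function(reconstruction, observed, n = 10000L,
                               rng_seed = 1L) {
  universe <- rownames(reconstruction$node_states)
  if (is.null(universe)) stop("reconstruction lacks pair row names")
  observed <- unique(as.character(observed))
  missing <- setdiff(observed, universe)
  if (length(missing)) {
    stop("observed pair(s) not in universe: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (length(observed) > length(universe)) {
    stop("observed set larger than the universe")
  }
  ind <- .branch_gain_indicators(reconstruction)
  obs_idx <- match(observed, universe)
  obs_frac <- colSums(ind$gains[obs_idx, , drop = FALSE]) /
    colSums(ind$parent0[obs_idx, , drop = FALSE])  # 0/0 -> NaN
  m <- length(observed)
  set.seed(rng_seed)
  n <- as.integer(n)
  exceed <- numeric(ncol(ind$gains))
  for (r in seq_len(n)) {
    idx <- sample.int(length(universe), m)
    frac <- colSums(ind$gains[idx, , drop = FALSE]) /
      colSums(ind$parent0[idx, , drop = FALSE])
    exceed <- exceed + (!is.na(frac) & !is.na(obs_frac) & frac >= obs_frac)
  }
  p <- (1 + exceed) / (n + 1)
  p[is.na(obs_frac) | is.nan(obs_frac)] <- NA_real_
  data.frame(branch_id = colnames(ind$gains),
             observed_gain_fraction = ifelse(is.nan(obs_frac), NA_real_,
                                             obs_frac),
             p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}
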