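#' Simulate a STRING-like scored interaction network
#'
#' Draws an Erdos-Renyi graph with `round(mean_degree * n / 2)` edges and
#' attaches confidence scores from a configurable distribution. If the
#' giant component holds fewer than 90% of the nodes (rare at
#' `mean_degree >= 4`), smaller components are attached to it by one extra
#' edge each, deterministically under the seed.
#'
#' @param n_proteins Number of nodes (>= 2); ids `P0001`, `P0002`, ...
#' @param mean_degree Target mean degree (must be < `n_proteins`).
#' @param score_distribution Function `f(m)` returning `m` scores in
#'   \[0, 1\]; the default is a right-skewed Beta(1.2, 2) resembling
#'   STRING combined scores.
#' @param rng_seed Integer seed; the same seed reproduces the network
#'   byte-identically.
#' @return A [scored_network()].
#' @export
simulate_network <- function(n_proteins, mean_degree = 6,
                             score_distribution = function(m) rbeta(m, 1.2, 2),
                             rng_seed = 1L) {
  if (n_proteins < 2) stop("n_proteins must be at least 2")
  if (mean_degree >= n_proteins) stop("mean_degree must be below n_proteins")
  set.seed(rng_seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  m <- round(mean_degree * n_proteins / 2)
  g <- igraph::sample_gnm(n_proteins, m)
  comp <- igraph::components(g)
  if (max(comp$csize) < 0.9 * n_proteins) {
    giant <- which.max(comp$csize)
    anchor <- which(comp$membership == giant)[1]
    for (cid in setdiff(seq_len(comp$no), giant)) {
      g <- igraph::add_edges(g, c(which(comp$membership == cid)[1], anchor))
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  scores <- score_distribution(nrow(el))
  scores <- pmin(pmax(scores, 0), 1)
  scored_network(data.frame(protein_a = ids[el[, 1]],
                            protein_b = ids[el[, 2]],
                            score = scores, stringsAsFactors = FALSE),
                 nodes = ids)
}
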