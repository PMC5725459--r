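#' Random walk with restart over a scored network
#'
#' Iterates the fixed point `r = c*e + (1-c) * W %*% r`, where `c` is the
#' restart probability, `e` the uniform distribution over the seed nodes,
#' and `W` the column-normalized (score-weighted by default) adjacency.
#' Columns of isolated nodes redirect their mass to the seed distribution,
#' keeping `W` stochastic, so the score vector sums to 1 at every
#' iteration. Nodes unreachable from the seeds keep score exactly 0.
#'
#' @param network A [scored_network()].
#' @param seeds Character vector of seed node ids (non-empty, all present in
#'   the network; a missing seed is an error naming it).
#' @param restart_probability Restart probability `c` in (0, 1]; with `c = 1`
#'   the result is exactly the uniform seed vector.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter Iteration cap (warns if reached without convergence).
#' @param weighted Use edge scores as walk weights (default) or binary
#'   adjacency.
#' @return A list of class `propagation_result`: `score` (named vector
#'   summing to 1), `seeds`, `restart_probability`, `iterations`,
#'   `converged`.
#' @export
rwr <- function(network, seeds, restart_probability = 0.95, tol = 1e-10,
                max_iter = 10000L, weighted = TRUE) {
  stopifnot(restart_probability > 0, restart_probability <= 1)
  if (!length(seeds)) stop("seed set is empty")
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, network$nodes)
  if (length(missing)) {
    stop("seed node(s) not in network: ", paste(missing, collapse = ", "))
  }
  nodes <- network$nodes
  n <- length(nodes)
  A <- network_adjacency(network, weighted = weighted)
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  W <- A
  nz <- which(!dangling)
  if (length(nz)) {
    W[, nz] <- A[, nz] %*% Matrix::Diagonal(x = 1 / deg[nz])
  }
  e <- numeric(n); names(e) <- nodes
  e[seeds] <- 1 / length(seeds)
  cc <- restart_probability
  r <- e
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    spread <- as.vector(W %*% r)
    if (any(dangling)) spread <- spread + sum(r[dangling]) * e
    r_new <- cc * e + (1 - cc) * spread
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("rwr did not converge within ", max_iter, " iterations")
  names(r) <- nodes
  structure(list(score = r, seeds = seeds,
                 restart_probability = restart_probability,
                 iterations = iterations, converged = converged),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(paste0("propagation_result: %d nodes, %d seeds, c=%g, ",
                     "%d iterations (sum=%.9f)\n"),
              length(x$score), length(x$seeds), x$restart_probability,
              x$iterations, sum(x$score)))
  invisible(x)
}

#' Top-scoring extended protein set
#'
#' Ranks nodes with nonzero propagation score descending by score, breaking
#' ties by lexicographic node id, and returns the first
#' `ceiling(fraction * n_nonzero)` nodes. Seeds are ranked like any other
#' node. The selection is idempotent and invariant to the input ordering.
#'
#' @param result A `propagation_result` from [rwr()].
#' @param fraction Fraction of nonzero-score nodes to keep, in (0, 1].
#' @return Character vector of selected node ids (ranked).
#' @export
top_fraction <- function(result, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  sc <- result$score[result$score > 0]
  if (!length(sc)) return(character(0))
  ord <- order(-sc, names(sc))
  n_sel <- ceiling(fraction * length(sc))
  names(sc)[ord][seq_len(n_sel)]
}

#' Ranked propagation score table
#'
#' @param result A `propagation_result`.
#' @return Data frame `protein`, `score`, `rank`, `is_seed` sorted by rank
#'   (score descending, ties by id).
#' @export
propagation_table <- function(result) {
  ord <- order(-result$score, names(result$score))
  data.frame(protein = names(result$score)[ord],
             score = unname(result$score[ord]),
             rank = seq_along(result$score),
             is_seed = names(result$score)[ord] %in% result$seeds,
             row.names = NULL, stringsAsFactors = FALSE)
}
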