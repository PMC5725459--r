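#' Term over-representation by the hypergeometric test
#'
#' One-sided (upper-tail) hypergeometric p-value per term for the
#' over-representation of a foreground gene set within a background, with
#' Bonferroni adjustment over the number of tested terms (terms with at
#' least one background gene). A term is enriched when its adjusted p-value
#' is below `alpha`.
#'
#' @param foreground Character vector of genes, a subset of `background`.
#' @param background Character vector of genes (the gene universe).
#' @param term_map Data frame with columns `term_id`, `gene_id`.
#' @param alpha Cutoff on the Bonferroni-adjusted p-value (default 0.05).
#' @return Data frame with one row per tested term: `term_id`, `k` (term
#'   genes in foreground), `K` (term genes in background), `n` (foreground
#'   size), `N` (background size), `raw_p`, `adj_p`, `enriched`.
#' @export
term_enrichment <- function(foreground, background, term_map, alpha = 0.05) {
  background <- unique(background)
  foreground <- unique(foreground)
  if (!length(background)) stop("empty background gene set")
  if (!all(foreground %in% background)) {
    stop("foreground genes missing from background: ",
         paste(head(setdiff(foreground, background), 5), collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(tm$term_id)
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(terms, function(t) {
    term_genes <- unique(tm$gene_id[tm$term_id == t])
    K <- length(term_genes)
    k <- length(intersect(term_genes, foreground))
    raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, raw_p = raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), raw_p = numeric())
  }
  out$adj_p <- pmin(1, out$raw_p * nrow(out))
  out$enriched <- out$adj_p < alpha
  out[order(out$adj_p, out$term_id), , drop = FALSE]
}
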