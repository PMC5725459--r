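#' Construct a scored protein-interaction network
#'
#' An undirected graph whose edges carry a confidence score in \[0, 1\]
#' (STRING-style). Edges are stored with lexicographically ordered endpoints;
#' self-loops are dropped with a message and duplicate pairs are merged
#' keeping the maximum score.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`.
#' @param nodes Optional character vector of node ids; endpoints of `edges`
#'   are always included, so this only adds isolated nodes.
#' @return A list of class `scored_network` with elements `edges` (data
#'   frame) and `nodes` (sorted character vector). Attributes `n_self_loops`
#'   and `n_merged` count dropped/merged input rows.
#' @export
scored_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b", "score") %in% names(edges)))
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  s <- as.numeric(edges$score)
  if (anyNA(s) || any(s < 0 | s > 1)) {
    bad <- which(is.na(s) | s < 0 | s > 1)[1]
    stop("edge score outside [0,1] at row ", bad)
  }
  self <- a == b
  n_self <- sum(self)
  if (n_self > 0) {
    message(n_self, " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  n_merged <- 0L
  if (anyDuplicated(key)) {
    n_merged <- sum(duplicated(key))
    message(n_merged, " duplicate pair(s) merged (max score kept)")
    s <- tapply(s, key, max)
    parts <- strsplit(names(s), "\r", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    s <- unname(s)
  }
  ord <- order(a, b)
  ed <- data.frame(protein_a = a[ord], protein_b = b[ord], score = s[ord],
                   stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(ed$protein_a, ed$protein_b, as.character(nodes))))
  structure(list(edges = ed, nodes = all_nodes),
            class = "scored_network",
            n_self_loops = n_self, n_merged = n_merged)
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored_network: %d nodes, %d edges (scores %s)\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) sprintf("%.2f-%.2f", min(x$edges$score),
                                         max(x$edges$score)) else "-"))
  invisible(x)
}

#' Read a scored edge list from a TSV file
#'
#' Expects three tab-separated columns: `protein1`, `protein2`, `score`
#' (header optional). Scores outside \[0, 1\] raise an error naming the line;
#' when both orientations of a pair occur the maximum score is kept and the
#' merge is reported.
#'
#' @param path Path to the TSV file.
#' @return A [scored_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(scored_network(
    data.frame(protein_a = character(), protein_b = character(),
               score = numeric())))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) {
    return(scored_network(data.frame(protein_a = character(),
                                     protein_b = character(),
                                     score = numeric())))
  }
  fields <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed edge line ", which(nf < 3)[1] + start - 1L,
         ": expected 3 tab-separated fields")
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | s < 0 | s > 1)
  if (length(bad)) {
    stop("score outside [0,1] (or unparsable) at line ", bad[1] + start - 1L)
  }
  scored_network(data.frame(protein_a = a, protein_b = b, score = s,
                            stringsAsFactors = FALSE))
}

#' Write a scored network as a TSV edge list
#'
#' @param network A `scored_network`.
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @export
write_edge_list <- function(network, path, header = TRUE) {
  lines <- sprintf("%s\t%s\t%s", network$edges$protein_a,
                   network$edges$protein_b,
                   format(network$edges$score, trim = TRUE, digits = 15))
  if (header) lines <- c("protein1\tprotein2\tscore", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network in Cytoscape SIF format
#'
#' One `proteinA pp proteinB` line per edge.
#'
#' @param network A `scored_network`.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  writeLines(sprintf("%s\tpp\t%s", network$edges$protein_a,
                     network$edges$protein_b), path)
  invisible(path)
}

# Sparse symmetric adjacency (weighted by score or binary), nodes in
# network$nodes order.
network_adjacency <- function(network, weighted = TRUE) {
  nodes <- network$nodes
  n <- length(nodes)
  i <- match(network$edges$protein_a, nodes)
  j <- match(network$edges$protein_b, nodes)
  w <- if (weighted) network$edges$score else rep(1, length(i))
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                       dims = c(n, n), dimnames = list(nodes, nodes))
}

# Fast membership keys for unordered pairs.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
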