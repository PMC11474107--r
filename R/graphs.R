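# Relationship-graph construction: threshold the similarity matrix, backfill
# nodes left with fewer than k information sources, add self-loops, and
# symmetrically normalize.
#
# Orientation convention: adjacency entry (i, j) is the weight with which
# node i collects information from node j. A row of the adjacency therefore
# lists a node's information sources, and the degree matrix of the
# normalization sums over sources.

#' Create a relationship graph from an adjacency matrix
#'
#' @param node_ids ordered node ids.
#' @param adjacency square matrix; entry (i, j) is the weight node i collects
#'   from node j (0 = no edge).
#' @return an object of class `relationship_graph`.
#' @export
relationship_graph <- function(node_ids, adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- length(node_ids)
  if (nrow(adjacency) != n || ncol(adjacency) != n) {
    input_error("adjacency must be %d x %d", n, n)
  }
  if (any(!is.finite(adjacency)) || any(adjacency < 0) || any(adjacency > 1)) {
    input_error("edge weights must lie in [0, 1]")
  }
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(node_ids = as.character(node_ids), adjacency = adjacency),
            class = "relationship_graph")
}

#' @export
print.relationship_graph <- function(x, ...) {
  off <- x$adjacency; diag(off) <- 0
  cat(sprintf("relationship_graph: %d nodes, %d directed edges\n",
              length(x$node_ids), sum(off > 0)))
  invisible(x)
}

#' Threshold a similarity matrix into a directed graph
#'
#' Keeps the off-diagonal entry (i, j) iff `S(i, j) >= delta`; kept edges
#' carry their similarity as weight and mean that node i may collect from
#' node j. The diagonal is left at 0 (self-loops are added later in the
#' pipeline).
#'
#' @param S a `similarity_matrix`.
#' @param delta threshold in `[0, 1]`.
#' @return a `relationship_graph`.
#' @export
threshold_edges <- function(S, delta) {
  stopifnot(inherits(S, "similarity_matrix"))
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1) {
    config_error("delta must lie in [0, 1], got %s", format(delta))
  }
  a <- S$values
  a[a < delta] <- 0
  diag(a) <- 0
  relationship_graph(S$entity_ids, a)
}

#' Backfill nodes to at least k information sources
#'
#' Every node whose thresholded row has fewer than `min(k, N - 1)` nonzero
#' off-diagonal entries (in-neighbours, i.e. information sources) gains
#' edges from its most similar non-neighbours, carrying their original
#' (sub-threshold) similarity weights. Ties are broken by descending
#' similarity, then ascending node index, so the result is deterministic.
#'
#' @param G a `relationship_graph` thresholded from `S`.
#' @param S the `similarity_matrix` `G` was built from.
#' @param k minimum number of information sources (k = 0 leaves G unchanged).
#' @return a `relationship_graph`.
#' @export
knn_backfill <- function(G, S, k) {
  stopifnot(inherits(G, "relationship_graph"), inherits(S, "similarity_matrix"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    config_error("k must be a non-negative integer")
  }
  a <- G$adjacency
  n <- nrow(a)
  need <- min(k, n - 1)
  for (i in seq_len(n)) {
    sources <- which(a[i, ] > 0 & seq_len(n) != i)
    deficit <- need - length(sources)
    if (deficit <= 0) next
    candidates <- setdiff(seq_len(n), c(i, sources))
    ord <- candidates[order(-S$values[i, candidates], candidates)]
    add <- ord[seq_len(deficit)]
    a[i, add] <- S$values[i, add]
  }
  relationship_graph(G$node_ids, a)
}

#' Add unit self-loops
#'
#' Sets the diagonal to 1 (a molecule's self-similarity under any of the
#' kernels), leaving off-diagonal entries untouched. Required so the degree
#' matrix of the normalization is invertible. Idempotent.
#'
#' @param G a `relationship_graph`.
#' @return a `relationship_graph`.
#' @export
add_self_loops <- function(G) {
  stopifnot(inherits(G, "relationship_graph"))
  a <- G$adjacency
  diag(a) <- 1
  relationship_graph(G$node_ids, a)
}

#' Symmetric degree normalization of a weighted adjacency
#'
#' Returns `D^{-1/2} A D^{-1/2}` with `D` the diagonal matrix of row sums of
#' the adjacency, computed as written even when the adjacency is asymmetric.
#'
#' @param G a `relationship_graph` with strictly positive row sums (use
#'   [add_self_loops()] first).
#' @return an object of class `normalized_adjacency`: list with `values`
#'   (the normalized matrix) and `graph` (the source graph).
#' @export
normalize_adjacency <- function(G) {
  stopifnot(inherits(G, "relationship_graph"))
  d <- rowSums(G$adjacency)
  if (any(d <= 0)) {
    domain_error(paste0("zero row sum at node '%s'; add self-loops before ",
                        "normalizing"), G$node_ids[which(d <= 0)[1]])
  }
  s <- 1 / sqrt(d)
  values <- G$adjacency * outer(s, s)
  structure(list(values = values, graph = G), class = "normalized_adjacency")
}

#' @export
print.normalized_adjacency <- function(x, ...) {
  cat(sprintf("normalized_adjacency: %d nodes\n", nrow(x$values)))
  invisible(x)
}

#' Build a relationship graph from a similarity matrix
#'
#' Runs the full pipeline threshold -> k-NN backfill -> self-loops ->
#' symmetric normalization. With `symmetric = TRUE` (protein graphs built
#' from a symmetric similarity) backfilled edges are added in both
#' directions, so the adjacency equals its transpose.
#'
#' @param S a `similarity_matrix`.
#' @param delta similarity threshold.
#' @param k backfill floor (default 5).
#' @param symmetric build an undirected graph; requires a symmetric `S`.
#' @return a list with components `graph` (the `relationship_graph` after
#'   self-loops) and `normalized` (its `normalized_adjacency`).
#' @export
build_relationship_graph <- function(S, delta, k = 5, symmetric = FALSE) {
  if (symmetric && !S$symmetric) {
    input_error("symmetric graph requested from an asymmetric similarity matrix")
  }
  g <- knn_backfill(threshold_edges(S, delta), S, k)
  if (symmetric) {
    a <- pmax(g$adjacency, t(g$adjacency))
    g <- relationship_graph(g$node_ids, a)
  }
  g <- add_self_loops(g)
  list(graph = g, normalized = normalize_adjacency(g))
}

#' Export / import a graph as a weighted edge list
#'
#' The TSV has columns `src`, `dst`, `weight`: information flows from `src`
#' to `dst`, i.e. `adjacency[dst, src] = weight`. Self-loops are included.
#'
#' @param G a `relationship_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(G, path) {
  stopifnot(inherits(G, "relationship_graph"))
  idx <- which(G$adjacency > 0, arr.ind = TRUE)
  df <- data.frame(
    src = G$node_ids[idx[, 2]], dst = G$node_ids[idx[, 1]],
    weight = formatC(G$adjacency[idx], format = "g", digits = 17),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$src, df$dst), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param node_ids node ordering of the reconstructed graph; defaults to the
#'   sorted union of ids present in the file.
#' @export
read_edge_list <- function(path, node_ids = NULL) {
  df <- read_table_auto(path)
  if (is.null(node_ids)) node_ids <- sort(unique(c(df$src, df$dst)))
  a <- matrix(0, length(node_ids), length(node_ids),
              dimnames = list(node_ids, node_ids))
  a[cbind(match(df$dst, node_ids), match(df$src, node_ids))] <-
    as.numeric(df$weight)
  relationship_graph(node_ids, a)
}

#' Export / import a graph as a square CSV adjacency matrix
#'
#' @param G a `relationship_graph`.
#' @param path file path.
#' @export
write_adjacency <- function(G, path) {
  stopifnot(inherits(G, "relationship_graph"))
  df <- data.frame(id = G$node_ids,
                   formatC(G$adjacency, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", G$node_ids)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1]])
  a <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(a) <- "double"
  relationship_graph(ids, a)
}
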