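# Relationship-graph construction: thresholding, k-NN backfill, self-loops,
# normalization, the full pipeline and its exports.

random_similarity <- function(n, seed, symmetric = FALSE) {
  set.seed(seed)
  v <- matrix(runif(n * n), n, n)
  if (symmetric) v <- (v + t(v)) / 2
  diag(v) <- 1
  new_similarity_matrix(sprintf("n%02d", seq_len(n)), v,
                        if (symmetric) "precomputed" else "sis")
}

test_that("thresholding keeps exactly the edges at or above delta", {
  S <- random_similarity(6, seed = 1)
  g0 <- threshold_edges(S, 0)
  off <- S$values; diag(off) <- 0
  expect_equal(g0$adjacency, off)  # complete weighted digraph

  g1 <- threshold_edges(S, 1)
  expect_true(all(g1$adjacency[g1$adjacency > 0] == 1))

  v <- diag(2); v[1, 2] <- 0.9; v[2, 1] <- 0.3
  S2 <- new_similarity_matrix(c("a", "b"), v, "sis")
  g <- threshold_edges(S2, 0.6)
  expect_equal(g$adjacency["a", "b"], 0.9)  # a collects from b
  expect_equal(g$adjacency["b", "a"], 0)    # one-way edge only

  expect_error(threshold_edges(S, 1.5), class = "sisdta_config_error")
  expect_error(threshold_edges(S, -0.1), class = "sisdta_config_error")
})

test_that("raising delta never adds an edge (monotone nesting)", {
  S <- random_similarity(10, seed = 2)
  deltas <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  prev <- threshold_edges(S, deltas[1])$adjacency > 0
  for (d in deltas[-1]) {
    cur <- threshold_edges(S, d)$adjacency > 0
    expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("backfill restores the in-degree floor with original weights", {
  S <- random_similarity(6, seed = 3)
  g <- threshold_edges(S, 0.9)
  gb <- knn_backfill(g, S, 2)
  for (i in 1:6) {
    sources <- which(gb$adjacency[i, ] > 0)
    expect_gte(length(sources), 2)
    # brute-force top-2: every backfilled source must carry its S weight
    expect_equal(gb$adjacency[i, sources], S$values[i, sources])
  }
  # node with no surviving neighbours and k = 1 gains exactly its argmax
  g1 <- knn_backfill(threshold_edges(S, 1), S, 1)
  for (i in 1:6) {
    srcs <- setdiff(which(g1$adjacency[i, ] > 0), i)
    if (length(srcs) == 1) {
      others <- setdiff(1:6, i)
      expect_equal(S$values[i, srcs], max(S$values[i, others]))
    }
  }
  # k = 0 leaves the graph unchanged
  expect_identical(knn_backfill(g, S, 0)$adjacency, g$adjacency)
  # existing edges are untouched
  g05 <- threshold_edges(S, 0.5)
  gb2 <- knn_backfill(g05, S, 3)
  kept <- g05$adjacency > 0
  expect_identical(gb2$adjacency[kept], g05$adjacency[kept])
})

test_that("backfill matches brute-force top-k selection when all edges dropped", {
  S <- random_similarity(6, seed = 4)
  gb <- knn_backfill(threshold_edges(S, 0.999999), S, 2)
  for (i in 1:6) {
    others <- setdiff(1:6, i)
    expected <- others[order(-S$values[i, others], others)][1:2]
    got <- setdiff(which(gb$adjacency[i, ] > 0), i)
    expect_setequal(got, expected)
  }
})

test_that("backfill tie-breaking is deterministic: similarity desc, index asc", {
  v <- matrix(0.5, 4, 4); diag(v) <- 1
  S <- new_similarity_matrix(letters[1:4], v, "precomputed")
  g <- knn_backfill(threshold_edges(S, 0.9), S, 2)
  # all candidates tie at 0.5, so the two lowest indices win
  expect_setequal(which(g$adjacency[3, ] > 0), c(1, 2))
  expect_setequal(which(g$adjacency[1, ] > 0), c(2, 3))
  g2 <- knn_backfill(threshold_edges(S, 0.9), S, 2)
  expect_identical(g$adjacency, g2$adjacency)
})

test_that("self-loops set the diagonal to 1 and are idempotent", {
  z <- relationship_graph(c("a", "b"), matrix(0, 2, 2))
  expect_equal(unname(add_self_loops(z)$adjacency), diag(2))
  S <- random_similarity(5, seed = 5)
  g <- add_self_loops(threshold_edges(S, 0.4))
  expect_identical(add_self_loops(g)$adjacency, g$adjacency)
  pre <- threshold_edges(S, 0.4)
  expect_equal(rowSums(g$adjacency) - rowSums(pre$adjacency),
               1 - diag(pre$adjacency), ignore_attr = TRUE)
})

test_that("normalization equals the dense D^-1/2 A D^-1/2 oracle", {
  I5 <- relationship_graph(letters[1:5], diag(5))
  expect_equal(unname(normalize_adjacency(I5)$values), diag(5))

  ones <- relationship_graph(c("a", "b"), matrix(1, 2, 2))
  expect_equal(unname(normalize_adjacency(ones)$values), matrix(0.5, 2, 2))

  set.seed(6)
  a <- matrix(runif(25, 0.01, 1), 5, 5)
  g <- relationship_graph(letters[1:5], a)
  d <- diag(1 / sqrt(rowSums(a)))
  expect_equal(unname(normalize_adjacency(g)$values), d %*% a %*% d,
               tolerance = 1e-14)

  zero_row <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  gz <- relationship_graph(c("a", "b"), zero_row)
  expect_error(normalize_adjacency(gz), "self-loop", class = "sisdta_domain_error")
})

test_that("the full pipeline respects symmetry and the in-degree floor", {
  S <- random_similarity(12, seed = 7, symmetric = TRUE)
  g <- build_relationship_graph(S, delta = 0.7, k = 3, symmetric = TRUE)
  expect_equal(g$graph$adjacency, t(g$graph$adjacency))
  expect_equal(g$normalized$values, t(g$normalized$values), tolerance = 1e-14)

  Sd <- random_similarity(20, seed = 8)
  gd <- build_relationship_graph(Sd, delta = 0.95, k = 5)
  indeg <- rowSums(gd$graph$adjacency > 0) - 1  # self-loops excluded
  expect_true(all(indeg >= 5))

  # delta = 0, k = 0: normalized complete graph matches the dense oracle
  gc <- build_relationship_graph(Sd, delta = 0, k = 0)
  a <- Sd$values  # complete + unit diagonal
  dd <- diag(1 / sqrt(rowSums(a)))
  expect_equal(unname(gc$normalized$values), dd %*% a %*% dd, tolerance = 1e-14)

  expect_error(build_relationship_graph(Sd, delta = 0.5, symmetric = TRUE),
               class = "sisdta_input_error")
})

test_that("pipeline commutes with transposition for symmetric input", {
  S <- random_similarity(9, seed = 9, symmetric = TRUE)
  g <- build_relationship_graph(S, delta = 0.8, k = 2, symmetric = TRUE)
  St <- new_similarity_matrix(S$entity_ids, t(S$values), S$kind)
  gt <- build_relationship_graph(St, delta = 0.8, k = 2, symmetric = TRUE)
  expect_equal(g$graph$adjacency, t(gt$graph$adjacency))
})

test_that("the SIS orientation lets the superset drug collect with weight 1", {
  sets <- substructure_sets(c(benzene = "c1ccccc1", phenol = "Oc1ccccc1",
                              toluene = "Cc1ccccc1", ethanol = "CCO"))
  S <- sis_matrix(sets)
  g <- build_relationship_graph(S, delta = 0.6, k = 0)
  # phenol contains benzene: the phenol row collects benzene with weight 1
  expect_equal(g$graph$adjacency["phenol", "benzene"], 1)
  # the reverse direction (3/11 = 0.27 < 0.6) was discarded
  expect_equal(g$graph$adjacency["benzene", "phenol"], 0)
  # normalized entry (benzene collects from phenol) < (phenol collects from benzene)
  expect_lt(g$normalized$values["benzene", "phenol"],
            g$normalized$values["phenol", "benzene"])
})

test_that("graphs round-trip through edge-list TSV and adjacency CSV", {
  S <- random_similarity(7, seed = 10)
  g <- build_relationship_graph(S, delta = 0.5, k = 2)$graph
  tsv <- tempfile(fileext = ".tsv"); csv <- tempfile(fileext = ".csv")
  write_edge_list(g, tsv)
  g2 <- read_edge_list(tsv, node_ids = g$node_ids)
  expect_identical(g2$adjacency, g$adjacency)
  write_adjacency(g, csv)
  g3 <- read_adjacency(csv)
  expect_identical(g3$adjacency, g$adjacency)
  # edge-list orientation: src is the information source
  df <- read.delim(tsv)
  i <- which(df$src == "n02" & df$dst == "n01")
  if (length(i) == 1) expect_equal(df$weight[i], g$adjacency["n01", "n02"])
  unlink(c(tsv, csv))
})
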