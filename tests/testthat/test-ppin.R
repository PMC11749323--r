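test_that("network assembly keeps query-adjacent edges and flags added genes", {
  et <- data.frame(geneA = c("A", "C", "A", "A"),
                   geneB = c("B", "D", "X", "A"),
                   interaction_type = c("physical", "physical", "physical",
                                        "physical"),
                   stringsAsFactors = FALSE)
  expect_warning(nw <- build_network(c("A", "B", "Z"), et), "self-loop")
  expect_setequal(nw$nodes$name, c("A", "B", "Z", "X"))   # C-D excluded
  expect_equal(nrow(nw$edges), 2L)
  expect_equal(nw$nodes$origin[nw$nodes$name == "X"], "added")
  expect_equal(nw$nodes$origin[nw$nodes$name == "A"], "query")
  expect_true("Z" %in% nw$nodes$name)   # isolated query gene kept

  et2 <- data.frame(geneA = "A", geneB = "B", interaction_type = "genetic")
  expect_warning(nw2 <- build_network(c("A", "B"), et2), "no usable edges")
  expect_equal(nrow(nw2$edges), 0L)
})

test_that("MCL separates disconnected components and handles singletons", {
  et <- data.frame(geneA = c("a", "b", "c", "x", "y", "z"),
                   geneB = c("b", "c", "a", "y", "z", "x"))
  nw <- build_network(c("a", "b", "c", "x", "y", "z"), et)
  cl <- mcl(nw)
  expect_equal(cl$n_clusters, 2L)
  expect_length(unique(cl$partition[c("a", "b", "c")]), 1L)
  expect_length(unique(cl$partition[c("x", "y", "z")]), 1L)
  expect_false(cl$partition["a"] == cl$partition["x"])

  single <- build_network("solo", NULL) |> suppressWarnings()
  expect_equal(mcl(single)$n_clusters, 1L)
})

test_that("MCL splits two cliques joined by a single bridge edge", {
  cliq <- function(nodes) {
    p <- utils::combn(nodes, 2)
    data.frame(geneA = p[1, ], geneB = p[2, ], stringsAsFactors = FALSE)
  }
  left <- paste0("L", 1:6); right <- paste0("R", 1:6)
  et <- rbind(cliq(left), cliq(right),
              data.frame(geneA = "L1", geneB = "R1"))
  nw <- build_network(c(left, right), et)
  cl <- mcl(nw, inflation = 2.0)
  expect_equal(cl$n_clusters, 2L)
  expect_length(unique(cl$partition[left]), 1L)
  expect_length(unique(cl$partition[right]), 1L)
})

test_that("every MCL iterate keeps stochastic columns", {
  # re-run the update rule directly and check column sums each iteration
  pg <- gen_planted_graph(seed = 4, sizes = c(6L, 6L))
  nw <- build_network(names(pg$membership), pg$edges)
  A <- cardioreg:::network_adjacency(nw)
  diag(A) <- diag(A) + 1
  M <- sweep(A, 2, colSums(A), "/")
  for (i in 1:15) {
    M2 <- (M %*% M)^2
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-6] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    expect_equal(unname(colSums(M2)), rep(1, ncol(M2)), tolerance = 1e-9)
    M <- M2
  }
})

test_that("MCL clustering is invariant to node relabelling", {
  pg <- gen_planted_graph(seed = 9)
  nw <- build_network(names(pg$membership), pg$edges)
  cl <- mcl(nw)
  set.seed(15)
  perm <- sample(names(pg$membership))
  et2 <- pg$edges
  map <- stats::setNames(sprintf("Q%02d", seq_along(perm)), perm)
  et2$geneA <- unname(map[et2$geneA]); et2$geneB <- unname(map[et2$geneB])
  cl2 <- mcl(build_network(unname(map), et2))
  # same partition after renaming back
  back <- stats::setNames(cl2$partition[map[names(pg$membership)]],
                          names(pg$membership))
  tab <- table(cl$partition[names(pg$membership)], back)
  expect_equal(sum(tab > 0), length(unique(cl$partition)))
})

test_that("planted partitions are recovered exactly across seeds", {
  skip_if_not_installed("mclust")
  ok <- 0L
  for (s in 1:20) {
    pg <- gen_planted_graph(seed = s)
    cl <- mcl(build_network(names(pg$membership), pg$edges))
    ari <- mclust::adjustedRandIndex(cl$partition[names(pg$membership)],
                                     pg$membership)
    if (isTRUE(all.equal(ari, 1))) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("higher inflation yields at least as many clusters", {
  more <- 0L; fewer <- 0L
  for (s in 1:10) {
    pg <- gen_planted_graph(seed = 100 + s)
    nw <- build_network(names(pg$membership), pg$edges)
    n_lo <- mcl(nw, inflation = 1.4)$n_clusters
    n_hi <- mcl(nw, inflation = 4.0)$n_clusters
    if (n_hi >= n_lo) more <- more + 1L else fewer <- fewer + 1L
  }
  expect_gte(more, 9L)
})

test_that("cluster summaries count intra- and inter-cluster edges correctly", {
  et <- data.frame(geneA = c("a", "b", "c", "p", "q", "a"),
                   geneB = c("b", "c", "a", "q", "r", "p"))
  nw <- build_network(c("a", "b", "c", "p", "q", "r"), et)
  part <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                          c("a", "b", "c", "p", "q", "r"))
  cl <- structure(list(partition = part, n_clusters = 2L, converged = TRUE,
                       iterations = 0L), class = "mcl_clustering")
  s <- cluster_summary(cl, nw)
  expect_equal(s$clusters$n_nodes, c(3L, 3L))
  expect_equal(s$clusters$n_edges, c(3L, 2L))   # triangle and 3-node path
  expect_equal(s$n_inter_cluster_edges, 1L)
})

test_that("per-cluster edge counts match brute-force edge classification", {
  set.seed(77)
  pg <- gen_planted_graph(seed = 33, sizes = c(8L, 8L, 8L), p_in = 0.8,
                          p_out = 0.08)
  nw <- build_network(names(pg$membership), pg$edges)
  cl <- mcl(nw)
  s <- cluster_summary(cl, nw)
  for (k in s$clusters$cluster) {
    members <- names(cl$partition)[cl$partition == k]
    want <- sum(nw$edges$from %in% members & nw$edges$to %in% members)
    expect_equal(s$clusters$n_edges[s$clusters$cluster == k], want)
  }
  expect_equal(sum(s$clusters$n_edges) + s$n_inter_cluster_edges,
               nrow(nw$edges))
})
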