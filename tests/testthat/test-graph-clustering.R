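named_graph <- function(edges, vertices = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE, vertices = vertices)
  g
}

test_that("maximum cliques are enumerated, deduplicated and ordered", {
  tri <- named_graph(c("a","b", "b","c", "a","c", "c","d"))
  expect_equal(maximum_cliques(tri), list(c("a", "b", "c")))
  # K2,2: four maximum cliques of size 2 (the edges)
  k22 <- named_graph(c("a","c", "a","d", "b","c", "b","d"))
  expect_equal(maximum_cliques(k22),
               list(c("a","c"), c("a","d"), c("b","c"), c("b","d")))
  # two disjoint K4s both listed
  k4s <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  igraph::V(k4s)$name <- letters[1:8]
  expect_equal(maximum_cliques(k4s),
               list(letters[1:4], letters[5:8]))
  # edgeless graph: empty list
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("x", "y", "z")
  expect_equal(maximum_cliques(lone), list())
})

test_that("maximum cliques match brute-force subset enumeration", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.8))
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    expect_equal(maximum_cliques(g), brute_max_cliques(g))
  }
})

test_that("paraclique accretes high-connectivity vertices to fixpoint", {
  # K5 missing one edge: seed K4, the fifth vertex is adjacent to 3 >= 4-1
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- LETTERS[1:5]
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("A", "B")))
  run <- paraclique_cluster(g, 0, glom_factor = 1, min_clique_size = 3)
  expect_equal(run$clusters[[1]], LETTERS[1:5])
  # two disjoint K4s: both recovered regardless of starting index
  k4s <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  igraph::V(k4s)$name <- letters[1:8]
  for (idx in 0:1) {
    run <- paraclique_cluster(k4s, idx, glom_factor = 1, min_clique_size = 3)
    expect_setequal(lapply(run$clusters, sort),
                    list(letters[1:4], letters[5:8]))
  }
  expect_error(paraclique_cluster(k4s, 2, 1, 3), "2 maximum clique",
               class = "robustclust_validation_error")
})

test_that("paracliques satisfy the glom-factor density bound", {
  set.seed(43)
  for (i in 1:10) {
    g <- igraph::sample_gnp(12, 0.55)
    igraph::V(g)$name <- sprintf("v%02d", 1:12)
    if (igraph::ecount(g) == 0) next
    seed_size <- length(maximum_cliques(g)[[1]])
    if (seed_size < 3) next
    run <- paraclique_cluster(g, 0, glom_factor = 1, min_clique_size = 3)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    pc <- run$clusters[[1]]
    s <- length(pc)
    edges_in <- sum(adj[pc, pc]) / 2
    expect_gte(edges_in, choose(s, 2) - 1 * (s - seed_size))
  }
})

test_that("heavily overlapping maximum cliques give identical paracliques", {
  g <- k8_minus_matching()
  cliques <- maximum_cliques(g)
  expect_equal(length(cliques), 16L)
  expect_true(all(lengths(cliques) == 4L))
  runs <- lapply(seq_along(cliques) - 1L, function(i)
    paraclique_cluster(g, i, glom_factor = 1, min_clique_size = 3))
  memberships <- unique(lapply(runs, function(r) lapply(r$clusters, sort)))
  expect_length(memberships, 1L)
  expect_equal(memberships[[1]][[1]], letters[1:8])
})

test_that("NNN clusters k-NN topology and splits at articulation points", {
  # two blocks with high intra-similarity, low inter
  set.seed(47)
  ids <- sprintf("n%02d", 1:10)
  sim <- matrix(runif(100, 0, 0.2), 10, 10, dimnames = list(ids, ids))
  sim <- (sim + t(sim)) / 2
  sim[1:5, 1:5] <- 0.9; sim[6:10, 6:10] <- 0.9
  diag(sim) <- 1
  run <- nnn_cluster(sim, k = 3, clique_size = 3)
  expect_setequal(lapply(run$clusters, sort), list(ids[1:5], ids[6:10]))

  # barbell: two triangles joined through a cut vertex
  ids7 <- letters[1:7]
  bar <- matrix(0, 7, 7, dimnames = list(ids7, ids7))
  for (e in list(c("a","b"), c("a","c"), c("b","c"), c("c","d"), c("d","e"),
                 c("c","e"), c("d","f"), c("e","f")))  # c and f tie the parts
    bar[e[1], e[2]] <- bar[e[2], e[1]] <- 1
  run2 <- nnn_cluster(bar, k = 3, clique_size = 3)
  expect_gte(length(run2$clusters), 2L)
  # disjoint output even though an articulation vertex joins two components
  expect_equal(anyDuplicated(unlist(run2$clusters)), 0L)

  # triangle-free k-NN graph has no clique of size 3: zero clusters
  ring <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  for (e in list(c("a","b"), c("b","c"), c("c","d"), c("d","a")))
    ring[e[1], e[2]] <- ring[e[2], e[1]] <- 0.9
  run3 <- nnn_cluster(ring, k = 2, clique_size = 3)
  expect_length(run3$clusters, 0L)
  expect_error(robustness(run_collection(list(run3))),
               class = "robustclust_undefined_robustness")
  expect_error(nnn_cluster(ring, k = 4), class = "robustclust_validation_error")
  expect_error(nnn_cluster(ring, k = 2, clique_size = 4),
               class = "robustclust_validation_error")
})

test_that("no NNN cluster exceeds half the items", {
  set.seed(53)
  for (i in 1:5) {
    n <- 12
    ids <- sprintf("m%02d", 1:n)
    sim <- matrix(runif(n * n, 0.5, 1), n, n, dimnames = list(ids, ids))
    sim <- (sim + t(sim)) / 2; diag(sim) <- 1
    run <- nnn_cluster(sim, k = 5, clique_size = 3)
    if (length(run$clusters) > 0)
      expect_lte(max(lengths(run$clusters)), n / 2)
  }
})
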