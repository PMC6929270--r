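# Shared fixtures and independent oracles used across the test files.

# The elementary three-run example over items A..F whose pair scores are
# (A,B)=3/3, (C,D)=(E,F)=2/3 and six further pairs at 1/3.
fig_runs <- function() {
  run_collection(list(
    cluster_run(list(c("A", "B", "C", "D"), c("E", "F")), "run1", "s=1"),
    cluster_run(list(c("A", "B"), c("C", "D"), c("E", "F")), "run2", "s=2"),
    cluster_run(list(c("A", "B"), c("C", "E"), c("D", "F")), "run3", "s=3")),
    algorithm = "toy", dataset = "toy")
}

# Brute-force robustness: enumerate every C(n,2) pair of the universe, scan
# every run for co-membership, and average the scores of pairs seen at
# least once. Independent of count_pairs()'s aggregation path.
oracle_robustness <- function(rc) {
  uni <- sort(unique(unlist(lapply(rc$runs, function(r)
    unlist(r$clusters, use.names = FALSE)))))
  r <- length(rc$runs)
  t <- 0L; scores <- numeric()
  if (length(uni) >= 2L) {
    for (i in seq_len(length(uni) - 1L)) for (j in (i + 1L):length(uni)) {
      cnt <- sum(vapply(rc$runs, function(run)
        any(vapply(run$clusters, function(cl)
          all(c(uni[i], uni[j]) %in% cl), logical(1))), logical(1)))
      if (cnt > 0L) { t <- t + cnt; scores <- c(scores, cnt / r) }
    }
  }
  list(R = if (length(scores)) mean(scores) else NA_real_,
       t = t, d = length(scores))
}

# Random flat partition of `items` into about `k` groups.
random_run <- function(items, k, id) {
  memb <- sample.int(k, length(items), replace = TRUE)
  cluster_run(split(items, memb), run_id = id)
}

random_run_collection <- function(n_items, n_runs, k = max(2L, n_items %/% 2L)) {
  items <- sprintf("it%02d", seq_len(n_items))
  run_collection(lapply(seq_len(n_runs), function(i)
    random_run(items, k, sprintf("r%d", i))))
}

# Look up one pair's count in a pair_table (0 when absent).
pair_count <- function(pt, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  row <- pt$counts[pt$counts$item_a == lo & pt$counts$item_b == hi, ]
  if (nrow(row) == 0L) 0L else row$count
}

run_to_membership <- function(run, universe) {
  memb <- rep("unassigned", length(universe))
  names(memb) <- universe
  for (nm in names(run$clusters)) memb[run$clusters[[nm]]] <- nm
  memb
}

random_dissim <- function(n, ids = sprintf("g%02d", seq_len(n))) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(ids, ids)
  d
}

# All maximum cliques of an igraph by exhaustive subset enumeration
# (feasible up to ~12 vertices); returns sorted vertex-ID vectors in
# lexicographic order, empty for an edgeless graph.
brute_max_cliques <- function(g) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ids <- sort(rownames(adj))
  n <- length(ids)
  if (sum(adj) == 0) return(list())
  for (m in n:2) {
    found <- list()
    for (s in utils::combn(ids, m, simplify = FALSE)) {
      sub <- adj[s, s]
      if (all(sub[upper.tri(sub)] == 1)) found[[length(found) + 1L]] <- s
    }
    if (length(found) > 0L)
      return(found[order(vapply(found, paste, "", collapse = "\x01"))])
  }
  list()
}

# Size of the largest subset of `items` whose diameter is within `cap`.
qt_max_feasible_size <- function(d, items, cap) {
  for (m in length(items):2) {
    for (s in utils::combn(items, m, simplify = FALSE))
      if (max(d[s, s]) <= cap) return(m)
  }
  1L
}

# The suffix property of nested hierarchical cuts: every pair's set of
# co-clustering runs must be a contiguous suffix of the run order.
is_suffix_collection <- function(rc) {
  r <- length(rc$runs)
  pt <- count_pairs(rc)
  for (i in seq_len(pt$d)) {
    a <- pt$counts$item_a[i]; b <- pt$counts$item_b[i]
    hits <- vapply(rc$runs, function(run)
      any(vapply(run$clusters, function(cl) all(c(a, b) %in% cl), logical(1))),
      logical(1))
    first <- which(hits)[1L]
    if (!all(hits[first:r])) return(FALSE)
    if (sum(hits) != r - first + 1L) return(FALSE)
  }
  TRUE
}

# Closed-form robustness under the suffix property:
# R = sum_P (r - first_run(P) + 1) / (d * r).
suffix_closed_form_R <- function(rc) {
  r <- length(rc$runs)
  pt <- count_pairs(rc)
  firsts <- vapply(seq_len(pt$d), function(i) {
    a <- pt$counts$item_a[i]; b <- pt$counts$item_b[i]
    which(vapply(rc$runs, function(run)
      any(vapply(run$clusters, function(cl) all(c(a, b) %in% cl), logical(1))),
      logical(1)))[1L]
  }, integer(1))
  sum(r - firsts + 1) / (pt$d * r)
}

# K8 minus a perfect matching: every maximum clique (one endpoint per
# missing edge) overlaps every other heavily; the canonical paraclique
# stability fixture.
k8_minus_matching <- function() {
  g <- igraph::make_full_graph(8)
  igraph::V(g)$name <- letters[1:8]
  igraph::delete_edges(g, igraph::get_edge_ids(
    g, c("a", "b", "c", "d", "e", "f", "g", "h")))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
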