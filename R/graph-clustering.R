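# Graph-based clustering: maximum-clique enumeration, paraclique, and
# nearest-neighbor-network (NNN) clustering.

#' Enumerate all maximum cliques of a graph
#'
#' Returns every clique of maximum cardinality, deduplicated and ordered
#' lexicographically by their sorted vertex IDs, so the i-th maximum clique
#' of a given graph is well defined (paraclique sweeps vary the starting
#' clique by this index).
#'
#' @param graph A `correlation_graph` or an `igraph`.
#' @return A list of character vectors (sorted vertex IDs); empty for an
#'   edgeless graph.
#' @export
maximum_cliques <- function(graph) {
  g <- as_rc_graph(graph)
  if (igraph::ecount(g) == 0L) return(list())
  cl <- lapply(igraph::largest_cliques(g), function(v) sort(names(v)))
  cl <- unique(cl)
  keys <- vapply(cl, paste, "", collapse = "\x01")
  cl[order(keys)]
}

# Grow a paraclique from a seed clique: repeatedly admit the
# lexicographically smallest vertex adjacent to at least (current size - g)
# members, rescanning after every admission, until no vertex qualifies.
accrete_paraclique <- function(g, seed, glom) {
  members <- sort(seed)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ids <- rownames(adj)
  repeat {
    if (glom >= length(members)) break   # glom factor must stay below size
    outside <- setdiff(ids, members)
    if (length(outside) == 0L) break
    deg_in <- rowSums(adj[outside, members, drop = FALSE])
    ok <- outside[deg_in >= length(members) - glom]
    if (length(ok) == 0L) break
    members <- sort(c(members, min(ok)))
  }
  members
}

#' Paraclique clustering
#'
#' Extracts densely connected, nearly complete subgraphs: a maximum clique
#' is isolated and then augmented ("accreted") with outside vertices that
#' are adjacent to all but at most `glom_factor` of its current members,
#' rescanning until no vertex qualifies. The finished paraclique is removed
#' from the graph and the process repeats, seeding each subsequent
#' paraclique from the first maximum clique of the residual graph, until the
#' residual maximum clique falls below `min_clique_size` (or
#' `max_paracliques` is reached). Vertices in no paraclique are left
#' unclustered.
#'
#' The swept setting is `starting_clique_index`: which of the graph's
#' maximum cliques (in [maximum_cliques()] order, 0-based) seeds the first
#' paraclique. On correlation graphs of real expression data maximum
#' cliques tend to overlap heavily, so the choice typically has little
#' effect on the clusters -- the mechanism behind paraclique's high
#' robustness.
#'
#' @param graph A `correlation_graph` or an `igraph`.
#' @param starting_clique_index 0-based index into [maximum_cliques()] of
#'   the input graph.
#' @param glom_factor Maximum number of missing adjacencies tolerated per
#'   admitted vertex (must stay below the current paraclique size).
#' @param min_clique_size Stop once the residual graph's maximum clique is
#'   smaller than this.
#' @param max_paracliques Optional cap on the number of paracliques emitted.
#' @return A [cluster_run()] with `setting_value = "clique=<index>"`.
#' @export
paraclique_cluster <- function(graph, starting_clique_index = 0L,
                               glom_factor = 1L, min_clique_size = 5L,
                               max_paracliques = Inf) {
  g <- as_rc_graph(graph)
  stopifnot(glom_factor >= 1L, min_clique_size >= 3L)
  cliques <- maximum_cliques(g)
  if (starting_clique_index < 0L || starting_clique_index >= length(cliques))
    rc_error(sprintf(
      "starting_clique_index %d out of range: the graph has %d maximum clique(s)",
      starting_clique_index, length(cliques)),
      "robustclust_validation_error")
  clusters <- list()
  seed <- cliques[[starting_clique_index + 1L]]
  residual <- g
  repeat {
    if (length(seed) < min_clique_size) break
    pc <- accrete_paraclique(residual, seed, glom_factor)
    clusters[[length(clusters) + 1L]] <- pc
    if (length(clusters) >= max_paracliques) break
    residual <- igraph::delete_vertices(residual, pc)
    if (igraph::ecount(residual) == 0L) break
    nxt <- maximum_cliques(residual)
    if (length(nxt) == 0L) break
    seed <- nxt[[1L]]
  }
  names(clusters) <- paste0("paraclique", seq_along(clusters))
  cluster_run(clusters,
              run_id = sprintf("paraclique_c%d", starting_clique_index),
              setting_value = sprintf("clique=%d", starting_clique_index))
}

# Symmetrized k-nearest-neighbor graph: keep directed edge (u,v) when v is
# among u's k highest similarities (ties by ascending ID), then take the
# union of directions.
knn_graph <- function(similarity, k) {
  ids <- rownames(similarity)
  n <- length(ids)
  edges <- list()
  for (u in ids) {
    s <- similarity[u, setdiff(ids, u)]
    ord <- order(-s, names(s))
    nbr <- names(s)[ord][seq_len(k)]
    edges[[u]] <- data.frame(from = u, to = nbr, stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, edges)
  key <- ifelse(el$from < el$to, paste(el$from, el$to), paste(el$to, el$from))
  el <- el[!duplicated(key), , drop = FALSE]
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = ids))
}

split_at_articulations <- function(sub) {
  # vertex sets of the biconnected components; an articulation vertex is
  # shared between the components it joins
  if (igraph::vcount(sub) <= 2L || igraph::ecount(sub) == 0L)
    return(list(sort(igraph::V(sub)$name)))
  if (length(igraph::articulation_points(sub)) == 0L)
    return(list(sort(igraph::V(sub)$name)))
  bc <- igraph::biconnected_components(sub)
  lapply(bc$components, function(v) sort(names(v)))
}

split_oversized <- function(vset, g, cap) {
  if (length(vset) <= cap) return(list(vset))
  sub <- igraph::induced_subgraph(g, vset)
  pieces <- split_at_articulations(sub)
  if (length(pieces) == 1L) {
    # biconnected and still too large: remove the minimum-degree vertex
    # (ties by ID) and re-split; the removed vertex follows its
    # lexicographically smallest neighbor's component when that still
    # shrinks the piece, and becomes a singleton otherwise
    deg <- igraph::degree(sub)
    drop <- sort(names(deg)[deg == min(deg)])[1L]
    rest <- igraph::delete_vertices(sub, drop)
    comps <- igraph::components(rest)
    pieces <- split(names(comps$membership), comps$membership)
    nbrs <- sort(names(igraph::neighbors(sub, drop)))
    if (length(pieces) > 1L && length(nbrs) > 0L) {
      host <- which(vapply(pieces, function(p) nbrs[1L] %in% p, logical(1)))[1L]
      pieces[[host]] <- c(pieces[[host]], drop)
    } else {
      pieces[[length(pieces) + 1L]] <- drop
    }
    pieces <- lapply(pieces, sort)
  }
  unlist(lapply(pieces, split_oversized, g = g, cap = cap),
         recursive = FALSE)
}

#' Nearest-neighbor-network (NNN) clustering
#'
#' Clusters items via the topology of a symmetrized k-nearest-neighbor
#' graph: (1) connect each item to its `k` most similar items and take the
#' union of directions; (2) enumerate all cliques of exactly `clique_size`
#' in that graph; (3) merge cliques sharing at least one vertex into
#' preliminary networks; (4) divide each network at its articulation
#' points (the biconnected components); (5) recursively split any cluster
#' larger than half the items. An articulation vertex belongs to each
#' component it joins; because downstream pair counting requires disjoint
#' clusters, such a vertex is assigned to the first of its clusters in
#' deterministic order (clusters sorted by their smallest member ID).
#'
#' @param similarity Square symmetric similarity matrix with item dimnames
#'   (typically a Pearson correlation matrix).
#' @param k Neighborhood size, `clique_size - 1 <= k < n`.
#' @param clique_size Size of the seed cliques (small, typically 3 or 4).
#' @return A [cluster_run()] with `setting_value = "k=<k>"`. Items covered
#'   by no clique of the requested size are left unclustered; if none are
#'   covered the run has zero clusters (robustness is then undefined
#'   downstream).
#' @export
nnn_cluster <- function(similarity, k, clique_size = 3L) {
  stopifnot(is.matrix(similarity), !is.null(rownames(similarity)))
  n <- nrow(similarity)
  if (k >= n)
    rc_error(sprintf("k = %d must be smaller than the number of items (%d)",
                     k, n), "robustclust_validation_error")
  if (k < clique_size - 1L)
    rc_error("k must be at least clique_size - 1",
             "robustclust_validation_error")
  g <- knn_graph(similarity, k)
  cl <- igraph::cliques(g, min = clique_size, max = clique_size)
  if (length(cl) == 0L)
    return(cluster_run(list(), run_id = sprintf("nnn_k%d", k),
                       setting_value = sprintf("k=%d", k)))
  # merge overlapping cliques: union-find over vertices
  parent <- stats::setNames(rownames(similarity), rownames(similarity))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (cc in cl) {
    vs <- names(cc)
    r1 <- find(vs[1L])
    for (v in vs[-1L]) parent[[find(v)]] <- r1
  }
  covered <- unique(unlist(lapply(cl, names), use.names = FALSE))
  groups <- split(covered, vapply(covered, find, ""))
  cap <- floor(n / 2)
  clusters <- list()
  for (grp in groups) {
    sub <- igraph::induced_subgraph(g, grp)
    for (piece in split_at_articulations(sub))
      clusters <- c(clusters, split_oversized(piece, g, cap))
  }
  # deterministic order, then resolve shared articulation vertices
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1L),
                             -lengths(clusters))]
  seen <- character()
  clusters <- lapply(clusters, function(cl) { x <- setdiff(cl, seen)
    seen <<- c(seen, x); x })
  clusters <- clusters[lengths(clusters) > 0L]
  names(clusters) <- paste0("nnn", seq_along(clusters))
  cluster_run(clusters, run_id = sprintf("nnn_k%d", k),
              setting_value = sprintf("k=%d", k))
}
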