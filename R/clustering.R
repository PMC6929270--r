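# Partitional and hierarchical clustering methods whose settings are swept:
# agglomerative hierarchical (four linkages), k-means, QT clustering, SOM.

check_dissim <- function(dissim) {
  stopifnot(is.matrix(dissim))
  if (nrow(dissim) != ncol(dissim) ||
      !isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-10)))
    rc_error("dissimilarity matrix must be square and symmetric",
             "robustclust_validation_error")
  if (any(abs(diag(dissim)) > 1e-10))
    rc_error("dissimilarity matrix must have a zero diagonal",
             "robustclust_validation_error")
  if (is.null(rownames(dissim)))
    rc_error("dissimilarity matrix must carry item IDs as dimnames",
             "robustclust_validation_error")
  invisible(TRUE)
}

linkage_method <- function(linkage) {
  # ward maps to hclust's ward.D2 (Ward's minimum variance on squared
  # dissimilarities, the convention documented for this package)
  switch(match.arg(linkage, c("average", "complete", "mcquitty", "ward")),
         average = "average", complete = "complete",
         mcquitty = "mcquitty", ward = "ward.D2")
}

#' Fit an agglomerative hierarchical clustering tree
#'
#' Builds the dendrogram once so that a sweep over cluster counts can cut
#' the same tree repeatedly: pairs merged at some cut stay merged at every
#' coarser cut, which is the structural reason hierarchical methods score
#' highly on robustness.
#'
#' @param dissim Square symmetric dissimilarity matrix, zero diagonal, with
#'   item IDs as dimnames.
#' @param linkage One of `"average"` (UPGMA), `"complete"`, `"mcquitty"`
#'   (WPGMA), `"ward"` (Ward's minimum variance, squared-dissimilarity
#'   convention, i.e. `hclust`'s `ward.D2`).
#' @return An `hclust` object.
#' @export
hierarchical_tree <- function(dissim,
                              linkage = c("average", "complete", "mcquitty", "ward")) {
  check_dissim(dissim)
  hclust(as.dist(dissim), method = linkage_method(match.arg(linkage)))
}

#' Cut a hierarchical tree into a clustering run
#'
#' @param tree An `hclust` object from [hierarchical_tree()].
#' @param n_clusters Number of clusters; `1` yields one all-item cluster,
#'   `n` yields all singletons.
#' @param run_id,setting_value Run labels; `setting_value` defaults to
#'   `"k=<n_clusters>"`.
#' @return A [cluster_run()].
#' @export
cut_tree_run <- function(tree, n_clusters, run_id = NULL, setting_value = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (n_clusters < 1L || n_clusters > n)
    rc_error(sprintf("n_clusters must be in [1, %d]", n),
             "robustclust_validation_error")
  memb <- cutree(tree, k = n_clusters)
  clusters <- split(names(memb), memb)
  if (is.null(setting_value)) setting_value <- sprintf("k=%d", n_clusters)
  if (is.null(run_id)) run_id <- setting_value
  cluster_run(clusters, run_id = run_id, setting_value = setting_value)
}

#' Agglomerative hierarchical clustering
#'
#' Convenience wrapper: fit the tree with [hierarchical_tree()] and cut it
#' at `n_clusters` with [cut_tree_run()].
#'
#' @inheritParams hierarchical_tree
#' @inheritParams cut_tree_run
#' @return A [cluster_run()].
#' @export
hierarchical_cluster <- function(dissim, linkage = "average", n_clusters = 2L) {
  cut_tree_run(hierarchical_tree(dissim, linkage), n_clusters)
}

scale_gene_rows <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  s[s == 0] <- 1           # constant genes stay constant (at zero)
  (expr - m) / s
}

#' K-means clustering of an expression matrix
#'
#' Lloyd's algorithm on the gene rows: `k` centroids are chosen at random
#' among the genes and genes are iteratively reassigned to the nearest
#' centroid. By default each gene row is standardized (mean 0, sd 1) first,
#' so that squared Euclidean distance between genes is proportional to
#' `1 - r` and the centroid method groups by expression profile shape, the
#' same similarity structure the correlation-driven methods in this package
#' use; set `scale_rows = FALSE` to cluster absolute log2 levels instead.
#' Deterministic for a fixed `seed`. Clusters left empty at convergence are
#' dropped, so the run may contain fewer than `k` clusters; robustness
#' consumes only the resulting partition.
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene IDs.
#' @param k Number of centroids; must not exceed the number of genes.
#' @param seed Integer seed controlling centroid initialization.
#' @param iter_max Maximum Lloyd iterations.
#' @param nstart Number of random restarts; the best (lowest within-cluster
#'   sum of squares) solution is kept.
#' @param scale_rows Standardize each gene row before clustering.
#' @return A [cluster_run()] with `setting_value = "k=<k>"`.
#' @export
kmeans_cluster <- function(expr, k, seed = 1L, iter_max = 100L,
                           nstart = 10L, scale_rows = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- nrow(expr)
  if (k > n)
    rc_error(sprintf("k = %d exceeds the number of genes (%d)", k, n),
             "robustclust_validation_error")
  if (scale_rows) expr <- scale_gene_rows(expr)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fit <- suppressWarnings(kmeans(expr, centers = k, iter.max = iter_max,
                                 nstart = nstart, algorithm = "Lloyd"))
  memb <- fit$cluster
  clusters <- split(rownames(expr), memb)      # empty clusters vanish here
  cluster_run(clusters, run_id = sprintf("kmeans_k%d", k),
              setting_value = sprintf("k=%d", k))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Quality-threshold (QT) clustering
#'
#' Greedy partitioning under a hard diameter cap: a candidate cluster is
#' grown from every remaining item as seed, at each step adding the item
#' that minimizes the resulting cluster diameter (the maximum pairwise
#' dissimilarity) while keeping it at or below `max_diameter`; the largest
#' candidate is emitted, its items removed, and the process repeats until no
#' items remain. Deterministic: growth ties and largest-candidate ties are
#' broken by lexicographic item ID (for candidates, by the lexicographically
#' smallest seed ID).
#'
#' @param dissim Square symmetric dissimilarity matrix with item dimnames.
#' @param max_diameter Diameter cap (> 0), in the units of `dissim` (for the
#'   `1 - r` correlation dissimilarity, a cap of 0.3 means every in-cluster
#'   pair is correlated at or above 0.7).
#' @return A [cluster_run()] with `setting_value = "diam=<max_diameter>"`.
#' @export
qt_cluster <- function(dissim, max_diameter) {
  check_dissim(dissim)
  if (!is.numeric(max_diameter) || max_diameter <= 0)
    rc_error("`max_diameter` must be positive", "robustclust_validation_error")
  remaining <- sort(rownames(dissim))
  clusters <- list()
  while (length(remaining) > 0L) {
    best <- NULL
    for (seed in remaining) {          # remaining is sorted: ties favor low IDs
      cand <- qt_grow(seed, remaining, dissim, max_diameter)
      if (is.null(best) || length(cand) > length(best)) best <- cand
    }
    clusters[[length(clusters) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  cluster_run(clusters, run_id = sprintf("qt_d%g", max_diameter),
              setting_value = sprintf("diam=%g", max_diameter))
}

qt_grow <- function(seed, pool, dissim, max_diameter) {
  cand <- seed
  avail <- setdiff(pool, seed)
  diam <- 0
  while (length(avail) > 0L) {
    # diameter if each available item were added (avail sorted ascending,
    # so which.min takes the lexicographically first among ties)
    new_diam <- vapply(avail, function(it)
      max(diam, max(dissim[it, cand])), numeric(1))
    ok <- new_diam <= max_diameter
    if (!any(ok)) break
    pick <- which.min(ifelse(ok, new_diam, Inf))
    diam <- new_diam[pick]
    cand <- c(cand, avail[pick])
    avail <- avail[-pick]
  }
  cand
}

som_grid_coords <- function(rows, cols, topology) {
  ij <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  if (topology == "hexagonal") {
    x <- ij$col + 0.5 * (ij$row %% 2L)
    y <- ij$row * sqrt(3) / 2
  } else {
    x <- ij$col
    y <- ij$row
  }
  cbind(x = x, y = y)
}

#' Self-organizing map clustering
#'
#' Online (stochastic) SOM over the gene rows: a `grid_rows` x `grid_cols`
#' map of code vectors is trained by repeatedly presenting genes and pulling
#' the best-matching node and its grid neighborhood toward each. After
#' training, each gene is assigned to its best-matching node and every
#' non-empty node becomes one cluster. The training schedule is fixed:
#' `100 * n` item presentations (genes cycled in a seeded random order),
#' learning rate decaying linearly 0.05 to 0.01, and a Gaussian neighborhood
#' whose radius decays linearly from half the grid diagonal to 1. Code
#' vectors are initialized from randomly drawn genes. Bit-reproducible for a
#' fixed `seed`. Gene rows are standardized by default, as in
#' [kmeans_cluster()].
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene IDs.
#' @param grid_rows,grid_cols Map dimensions; their product must not exceed
#'   the number of genes.
#' @param topology `"rectangular"` or `"hexagonal"` node layout (hexagonal
#'   offsets alternate rows by half a unit, giving six equidistant
#'   neighbors).
#' @param seed Integer seed.
#' @param scale_rows Standardize each gene row before training.
#' @return A [cluster_run()] with `setting_value`
#'   `"<rows>x<cols>-<topology>"`.
#' @export
som_cluster <- function(expr, grid_rows, grid_cols,
                        topology = c("rectangular", "hexagonal"),
                        seed = 1L, scale_rows = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  topology <- match.arg(topology)
  if (scale_rows) expr <- scale_gene_rows(expr)
  n <- nrow(expr)
  n_nodes <- grid_rows * grid_cols
  if (n_nodes > n)
    rc_error(sprintf("grid of %d nodes exceeds the number of genes (%d)",
                     n_nodes, n), "robustclust_validation_error")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  coords <- som_grid_coords(grid_rows, grid_cols, topology)
  codebook <- expr[sample.int(n, n_nodes, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(n_nodes * ncol(expr), sd = 1e-3), n_nodes)
  epochs <- 100L
  total <- epochs * n
  r0 <- max(sqrt(sum((coords[1L, ] - coords[n_nodes, ])^2)) / 2, 1)
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      frac <- step / total
      lr <- 0.05 + (0.01 - 0.05) * frac
      sigma <- r0 + (1 - r0) * frac
      x <- expr[i, ]
      d2 <- rowSums(sweep(codebook, 2L, x)^2)
      bmu <- which.min(d2)               # ties: lowest node index
      g2 <- (coords[, "x"] - coords[bmu, "x"])^2 +
            (coords[, "y"] - coords[bmu, "y"])^2
      h <- lr * exp(-g2 / (2 * sigma^2))
      codebook <- codebook + h * (matrix(x, n_nodes, ncol(expr),
                                         byrow = TRUE) - codebook)
    }
  }
  assign_node <- vapply(seq_len(n), function(i)
    which.min(rowSums(sweep(codebook, 2L, expr[i, ])^2)), integer(1))
  clusters <- split(rownames(expr), assign_node)
  names(clusters) <- paste0("node", names(clusters))
  cluster_run(clusters,
              run_id = sprintf("som_%dx%d_%s", grid_rows, grid_cols, topology),
              setting_value = sprintf("%dx%d-%s", grid_rows, grid_cols, topology))
}
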