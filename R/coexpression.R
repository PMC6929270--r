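# Pearson co-expression graphs: correlation, hard thresholding at tau, and
# a spectral heuristic for proposing tau.

#' Pearson correlation matrix of an expression matrix
#'
#' Gene-by-gene Pearson product-moment correlations computed across samples.
#' Genes with zero variance must be removed first (their correlation is
#' undefined); they are reported by name if present.
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene IDs.
#' @return Symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
correlation_matrix <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L)
    rc_error("at least 3 samples are required for meaningful correlations",
             "robustclust_validation_error")
  rng <- apply(expr, 1L, function(x) max(x) - min(x))
  if (any(rng == 0))
    rc_error(sprintf("constant gene(s) present (undefined correlation): %s",
                     paste(sQuote(rownames(expr)[rng == 0]), collapse = ", ")),
             "robustclust_validation_error")
  cc <- cor(t(expr), method = "pearson")
  diag(cc) <- 1
  pmin(pmax(cc, -1), 1)
}

#' Correlation-based dissimilarity
#'
#' `1 - r`, the distance convention used for hierarchical and QT clustering
#' of co-expression data in this package: perfectly correlated genes are at
#' distance 0, perfectly anti-correlated genes at distance 2.
#'
#' @inheritParams correlation_matrix
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
correlation_dissimilarity <- function(expr) {
  d <- 1 - correlation_matrix(expr)
  diag(d) <- 0
  d
}

#' Hard-threshold a correlation matrix into a co-expression graph
#'
#' An edge is retained if and only if its weight is at or above the
#' threshold `tau` (signed comparison by default; set `absolute = TRUE` to
#' threshold `|weight|`, a convention some co-expression pipelines prefer).
#' All genes remain as vertices; genes whose every correlation falls below
#' `tau` become isolated vertices.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param tau Threshold in \[-1, 1\].
#' @param absolute Threshold on absolute weight instead of signed weight.
#' @return An object of class `correlation_graph`: list with `graph` (an
#'   `igraph` with vertex names and edge attribute `weight`), `tau`,
#'   `absolute`.
#' @export
threshold_graph <- function(corr, tau, absolute = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            !is.null(rownames(corr)))
  if (!is.numeric(tau) || length(tau) != 1L || tau < -1 || tau > 1)
    rc_error("`tau` must be a single value in [-1, 1]",
             "robustclust_validation_error")
  w <- if (absolute) abs(corr) else corr
  keep <- which(upper.tri(w) & w >= tau, arr.ind = TRUE)
  genes <- rownames(corr)
  edges <- data.frame(from = genes[keep[, 1L]], to = genes[keep[, 2L]],
                      weight = corr[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  structure(list(graph = g, tau = tau, absolute = absolute),
            class = "correlation_graph")
}

# Accept either a correlation_graph or a bare igraph where a graph is needed.
as_rc_graph <- function(x) {
  if (inherits(x, "correlation_graph")) return(x$graph)
  if (inherits(x, "igraph")) {
    if (is.null(igraph::V(x)$name))
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    return(x)
  }
  rc_error("expected a correlation_graph or an igraph object",
           "robustclust_validation_error")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph: %d vertices, %d edges, tau = %s%s>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$tau), if (x$absolute) " (absolute)" else ""))
  invisible(x)
}

#' Write a co-expression graph as a weighted edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight`. Isolated vertices are not
#' representable in an edge list and are omitted.
#'
#' @param graph A `correlation_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  g <- as_rc_graph(graph)
  el <- igraph::as_data_frame(g, what = "edges")
  colnames(el)[1:2] <- c("gene_a", "gene_b")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Propose a hard threshold from the correlation spectrum
#'
#' A heuristic threshold picker inspired by spectral approaches to network
#' thresholding: for each candidate `tau` the unweighted adjacency matrix at
#' that threshold is formed and its largest eigenvalue computed. As `tau`
#' rises the leading eigenvalue falls; the suggested threshold is the last
#' candidate before the relatively steepest decline (the largest drop in the
#' leading eigenvalue between consecutive candidates, relative to its value
#' before the drop) -- the highest threshold at which the network's dominant
#' connectivity is still intact. On a complete graph of identical weights
#' `w` this returns the largest candidate at or below `w` (the eigenvalue
#' collapses to zero at the first candidate above `w`); if the eigenvalue
#' never declines, the smallest candidate is returned.
#' The full per-candidate diagnostics table is returned so the
#' curve can be inspected; the suggestion is advisory, and every pipeline in
#' this package accepts a user-supplied `tau` instead.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param candidates Ascending candidate thresholds, each in \[0, 1\];
#'   at least 3 are required for an inflection to be definable.
#' @return An object of class `threshold_suggestion`: list with `tau` (the
#'   suggested threshold) and `diagnostics` (data.frame with columns `tau`,
#'   `n_edges`, `lambda_max`, `n_components`).
#' @export
suggest_threshold <- function(corr, candidates = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (length(candidates) < 3L)
    rc_error("at least 3 candidate thresholds are required",
             "robustclust_validation_error")
  if (is.unsorted(candidates) || any(candidates < 0 | candidates > 1))
    rc_error("`candidates` must be ascending and within [0, 1]",
             "robustclust_validation_error")
  n <- nrow(corr)
  diag_rows <- lapply(candidates, function(tau) {
    adj <- (corr >= tau) * 1
    diag(adj) <- 0
    lam <- if (sum(adj) == 0) 0 else max(eigen(adj, symmetric = TRUE,
                                               only.values = TRUE)$values)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    data.frame(tau = tau, n_edges = sum(adj) / 2, lambda_max = lam,
               n_components = igraph::count_components(g))
  })
  diags <- do.call(rbind, diag_rows)
  lam <- diags$lambda_max
  prev <- lam[-length(lam)]
  drop_rel <- (prev - lam[-1L]) / pmax(prev, .Machine$double.eps)
  pick <- if (all(drop_rel <= 0)) 1L else which.max(drop_rel)
  structure(list(tau = candidates[pick], diagnostics = diags),
            class = "threshold_suggestion")
}

#' @export
print.threshold_suggestion <- function(x, ...) {
  cat(sprintf("<threshold_suggestion> tau = %s\n", format(x$tau)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
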