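# The parameter-sweep harness: one clustering run per setting value, with
# everything else (including the seed) held fixed, so that the swept setting
# is the only varying factor entering the robustness computation.

#' Specify a parameter sweep for one algorithm
#'
#' @param algorithm One of `"average"`, `"complete"`, `"mcquitty"`, `"ward"`
#'   (hierarchical linkages, swept over cluster counts), `"kmeans"`,
#'   `"qt"` (max cluster diameter), `"som"` (grid size/topology, values like
#'   `"5x7-rectangular"`), `"paraclique"` (starting maximum-clique index),
#'   `"nnn"` (neighborhood size), or `"external"` (values are membership
#'   file paths produced by an outside tool, e.g. WGCNA or CLICK).
#' @param values Ordered setting values; each yields one run, so
#'   `r = length(values)`.
#' @param setting_name Label for the swept setting (defaults per algorithm).
#' @param fixed_params Named list of parameters held fixed across the sweep.
#'   Recognized entries include `input` (`"expression"`, the default, or
#'   `"dissimilarity"`/`"similarity"` when the data matrix is already one),
#'   `tau` and `glom_factor`/`min_clique_size`/`max_paracliques` for
#'   paraclique, `clique_size` for nnn, `distance` (`"correlation"`, the
#'   default, or `"euclidean"`) for hierarchical/qt, and
#'   `external_algorithm`/`exclude_labels` for external runs.
#' @param seed Integer seed propagated identically to every run.
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(algorithm, values, setting_name = NULL,
                       fixed_params = list(), seed = 1L) {
  algorithms <- c("average", "complete", "mcquitty", "ward",
                  "kmeans", "qt", "som", "paraclique", "nnn", "external")
  algorithm <- match.arg(algorithm, algorithms)
  if (length(values) < 1L)
    rc_error("`values` must be non-empty", "robustclust_validation_error")
  if (is.null(setting_name))
    setting_name <- switch(algorithm,
      average = , complete = , mcquitty = , ward = , kmeans = "n_clusters",
      qt = "max_diameter", som = "grid", paraclique = "starting_clique",
      nnn = "neighborhood_size", external = "file")
  structure(list(algorithm = algorithm, setting_name = setting_name,
                 values = values, fixed_params = fixed_params,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

fp <- function(spec, name, default) {
  v <- spec$fixed_params[[name]]
  if (is.null(v)) default else v
}

sweep_dissim <- function(spec, data) {
  if (identical(fp(spec, "input", "expression"), "dissimilarity")) {
    check_dissim(data)
    return(data)
  }
  if (identical(fp(spec, "distance", "correlation"), "euclidean"))
    as.matrix(dist(data)) else correlation_dissimilarity(data)
}

sweep_similarity <- function(spec, data) {
  if (identical(fp(spec, "input", "expression"), "similarity")) return(data)
  correlation_matrix(data)
}

parse_som_value <- function(value) {
  if (is.list(value) || (is.numeric(value) && length(value) >= 2L)) {
    v <- as.list(value)
    return(list(rows = as.integer(v[[1]]), cols = as.integer(v[[2]]),
                topology = if (length(v) >= 3L) as.character(v[[3]])
                           else "rectangular"))
  }
  m <- regmatches(value, regexec("^(\\d+)x(\\d+)-(rectangular|hexagonal)$",
                                 as.character(value)))[[1]]
  if (length(m) != 4L)
    rc_error(sprintf("cannot parse SOM grid value '%s' (want e.g. '5x7-rectangular')",
                     value), "robustclust_validation_error")
  list(rows = as.integer(m[2]), cols = as.integer(m[3]), topology = m[4])
}

sweep_one <- function(spec, data, value, precomputed) {
  switch(spec$algorithm,
    average = , complete = , mcquitty = , ward =
      cut_tree_run(precomputed$tree, as.integer(value)),
    kmeans = kmeans_cluster(data, as.integer(value), seed = spec$seed),
    qt = qt_cluster(precomputed$dissim, as.numeric(value)),
    som = {
      gv <- parse_som_value(value)
      som_cluster(data, gv$rows, gv$cols, topology = gv$topology,
                  seed = spec$seed)
    },
    paraclique = paraclique_cluster(
      precomputed$graph, starting_clique_index = as.integer(value),
      glom_factor = fp(spec, "glom_factor", 1L),
      min_clique_size = fp(spec, "min_clique_size", 5L),
      max_paracliques = fp(spec, "max_paracliques", Inf)),
    nnn = nnn_cluster(precomputed$similarity, as.integer(value),
                      clique_size = fp(spec, "clique_size", 3L)),
    external = ingest_external_run(
      as.character(value),
      algorithm = fp(spec, "external_algorithm", "external"),
      setting_value = as.character(value),
      exclude_labels = fp(spec, "exclude_labels", character()),
      allow_shared_singleton = fp(spec, "allow_shared_singleton", FALSE)))
}

#' Execute a parameter sweep
#'
#' Runs the algorithm named by `spec` once per setting value, on the same
#' data and with the same seed, producing the [run_collection()] over which
#' robustness is computed. Shared structures (the hierarchical tree, the
#' dissimilarity/similarity matrix, the thresholded graph) are computed once
#' per sweep.
#'
#' @param spec A [sweep_spec()].
#' @param data An expression matrix (genes x samples) by default; a
#'   dissimilarity or similarity matrix or a `correlation_graph` when the
#'   spec's `fixed_params$input` says so or the algorithm consumes a graph.
#' @param dataset Dataset label stored on the collection.
#' @return A [run_collection()] with one run per value, in order.
#' @export
run_sweep <- function(spec, data, dataset = "dataset") {
  stopifnot(inherits(spec, "sweep_spec"))
  precomputed <- list()
  if (spec$algorithm %in% c("average", "complete", "mcquitty", "ward"))
    precomputed$tree <- hierarchical_tree(sweep_dissim(spec, data),
                                          linkage = spec$algorithm)
  if (spec$algorithm == "qt")
    precomputed$dissim <- sweep_dissim(spec, data)
  if (spec$algorithm == "nnn")
    precomputed$similarity <- sweep_similarity(spec, data)
  if (spec$algorithm == "paraclique") {
    precomputed$graph <- if (inherits(data, c("correlation_graph", "igraph")))
      data
    else
      threshold_graph(correlation_matrix(data),
                      tau = fp(spec, "tau", 0.85))
  }
  runs <- lapply(seq_along(spec$values), function(i) {
    value <- if (is.list(spec$values)) spec$values[[i]] else spec$values[i]
    run <- tryCatch(sweep_one(spec, data, value, precomputed),
      robustclust_error = function(e)
        rc_error(sprintf("sweep value '%s' (%s) failed: %s",
                         paste(format(value), collapse = "x"),
                         spec$setting_name, conditionMessage(e)),
                 "robustclust_sweep_error"))
    run$run_id <- sprintf("%s_%02d", spec$algorithm, i)
    run$setting_value <- paste0(spec$setting_name, "=",
                                paste(format(value), collapse = "x"))
    run
  })
  run_collection(runs, algorithm = spec$algorithm, dataset = dataset)
}

#' Per-run diagnostics of a run collection
#'
#' Reports, per run, the number of clusters, the number of clustered items
#' and the mean cluster size -- the quantities used to judge whether sweeps
#' of different algorithms produce clusters "of the same scale" and are
#' therefore fairly comparable on robustness.
#'
#' @param runs A [run_collection()].
#' @return A data.frame with one row per run.
#' @export
run_diagnostics <- function(runs) {
  stopifnot(inherits(runs, "run_collection"))
  do.call(rbind, lapply(runs$runs, function(r) {
    sizes <- lengths(r$clusters)
    data.frame(run_id = r$run_id, setting_value = r$setting_value,
               n_clusters = length(sizes), n_items = sum(sizes),
               mean_cluster_size = if (length(sizes)) mean(sizes) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Robustness report across algorithms and datasets
#'
#' Runs every sweep spec on every dataset, computes robustness per
#' (algorithm, dataset) cell, and summarizes per algorithm with the mean and
#' coefficient of variation across datasets. A sweep that fails on one
#' dataset (an incompatible setting, a degenerate all-singleton result, a
#' timeout upstream) yields a missing cell and a logged failure, not an
#' aborted report; the algorithm's summary is computed over its remaining
#' cells.
#'
#' @param specs List of [sweep_spec()] objects (one per algorithm).
#' @param datasets Named list of data objects as accepted by [run_sweep()].
#' @return An object of class `robustness_report`: list with `table`
#'   (data.frame: algorithm, dataset, r, t, d, R -- `NA` for failed cells),
#'   `summaries` (named list of [summarize_robustness()] results), and
#'   `failures` (data.frame: algorithm, dataset, message).
#' @export
robustness_report <- function(specs, datasets) {
  if (inherits(specs, "sweep_spec")) specs <- list(specs)
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  rows <- list(); fails <- list(); summaries <- list()
  for (spec in specs) {
    per_ds <- list()
    for (ds in names(datasets)) {
      res <- tryCatch(robustness(run_sweep(spec, datasets[[ds]], dataset = ds)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          algorithm = spec$algorithm, dataset = ds,
          message = conditionMessage(res), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = spec$algorithm, dataset = ds, r = length(spec$values),
          t = NA_integer_, d = NA_integer_, R = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        per_ds[[ds]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = spec$algorithm, dataset = ds, r = res$r,
          t = res$t, d = res$d, R = res$R, stringsAsFactors = FALSE)
      }
    }
    if (length(per_ds) > 0L)
      summaries[[spec$algorithm]] <- summarize_robustness(per_ds)
  }
  structure(list(table = do.call(rbind, rows),
                 summaries = summaries,
                 failures = if (length(fails)) do.call(rbind, fails)
                            else data.frame(algorithm = character(),
                                            dataset = character(),
                                            message = character())),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  tab <- x$table
  tab$R <- ifelse(is.na(tab$R), NA, round(tab$R, 3))
  print(tab, row.names = FALSE)
  for (alg in names(x$summaries)) {
    s <- x$summaries[[alg]]
    cat(sprintf("  %s: mean R = %.3f, CV = %s\n", alg, s$mean_R,
                if (is.na(s$cv)) "NA" else sprintf("%.3f", s$cv)))
  }
  if (nrow(x$failures) > 0L)
    cat(sprintf("  %d failed cell(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Default sweep specifications mirroring common practice
#'
#' The settings conventionally swept per algorithm on genome-scale
#' co-expression data: cluster counts 200 to 300 (step 10, so r = 11) for
#' hierarchical, k-means and (as grid sizes) SOM; QT maximum diameters 0.05
#' to 0.5 in steps of 0.05; NNN neighborhood sizes 16 to 25; paraclique
#' starting-clique indices 0 to `n_paracliques - 1`. A `scale` factor
#' shrinks the cluster-count range proportionally for small matrices while
#' keeping r fixed.
#'
#' @param scale Multiplier applied to the 200-300 cluster-count range.
#' @param seed Seed stored on every spec.
#' @param tau Threshold for the paraclique graph construction.
#' @param n_paracliques How many starting-clique indices to sweep.
#' @return Named list of [sweep_spec()] objects.
#' @export
default_sweep_specs <- function(scale = 1, seed = 1L, tau = 0.85,
                                n_paracliques = 9L) {
  ks <- unique(pmax(2L, as.integer(round(seq(200, 300, by = 10) * scale))))
  grids <- vapply(unique(as.integer(round(seq(200, 300, length.out = 5) * scale))),
                  function(k) {
    r <- max(1L, as.integer(floor(sqrt(k))))
    sprintf("%dx%d", r, max(1L, as.integer(ceiling(k / r))))
  }, "")
  som_values <- c(paste0(grids, "-rectangular"), paste0(grids, "-hexagonal"))
  list(
    average = sweep_spec("average", ks, seed = seed),
    complete = sweep_spec("complete", ks, seed = seed),
    mcquitty = sweep_spec("mcquitty", ks, seed = seed),
    ward = sweep_spec("ward", ks, seed = seed),
    kmeans = sweep_spec("kmeans", ks, seed = seed),
    qt = sweep_spec("qt", seq(0.05, 0.5, by = 0.05), seed = seed),
    som = sweep_spec("som", som_values, seed = seed),
    nnn = sweep_spec("nnn", 16:25, seed = seed),
    paraclique = sweep_spec("paraclique", seq_len(n_paracliques) - 1L,
                            fixed_params = list(tau = tau), seed = seed))
}
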