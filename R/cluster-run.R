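#' @importFrom stats cor cutree hclust kmeans sd as.dist dist runif rnorm
#' @importFrom utils combn read.delim write.table packageVersion
#' @importFrom data.table data.table := .N
NULL

.datatable.aware <- TRUE

rc_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "robustclust_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct a single clustering run
#'
#' A run is one flat, non-overlapping clustering of a set of items, tagged
#' with the setting value that produced it. Singleton clusters are allowed;
#' they contribute no pairs to the robustness computation.
#'
#' @param clusters A list of character vectors, one per cluster. Names, if
#'   present, are used as cluster identifiers; otherwise clusters are numbered.
#' @param run_id A label for the run.
#' @param setting_value The value of the varied setting that produced this
#'   run (e.g. `"k=250"`), stored as a string.
#' @return An object of class `cluster_run`.
#' @examples
#' cluster_run(list(c("A", "B"), c("C", "D"), c("E", "F")), run_id = "run2")
#' @export
cluster_run <- function(clusters, run_id = "run", setting_value = NA_character_) {
  if (!is.list(clusters))
    rc_error("`clusters` must be a list of character vectors",
             "robustclust_validation_error")
  clusters <- lapply(clusters, as.character)
  if (any(lengths(clusters) < 1L))
    rc_error(sprintf("run '%s' contains an empty cluster", run_id),
             "robustclust_validation_error")
  if (is.null(names(clusters)))
    names(clusters) <- as.character(seq_along(clusters))
  all_items <- unlist(clusters, use.names = FALSE)
  dup <- unique(all_items[duplicated(all_items)])
  if (length(dup) > 0L)
    rc_error(sprintf(
      "run '%s' assigns item(s) %s to more than one cluster",
      run_id, paste(sQuote(dup), collapse = ", ")),
      "robustclust_validation_error")
  structure(
    list(run_id = as.character(run_id),
         setting_value = as.character(setting_value),
         clusters = clusters),
    class = "cluster_run")
}

#' Construct a collection of clustering runs
#'
#' The unit over which robustness is computed: the `r` runs of one algorithm
#' on one dataset, each run produced with a different value of the swept
#' setting. Runs need not cluster every item in the universe (paraclique, for
#' instance, leaves unclustered residue), and cluster identifiers are scoped
#' to a single run -- only co-membership within a run matters downstream.
#'
#' @param runs A list of [cluster_run()] objects, in sweep order.
#' @param algorithm Name of the clustering algorithm.
#' @param dataset Name of the dataset the runs were computed on.
#' @return An object of class `run_collection` with fields `algorithm`,
#'   `dataset` and `runs`.
#' @export
run_collection <- function(runs, algorithm = "unknown", dataset = "unknown") {
  if (length(runs) < 1L)
    rc_error("a run collection needs at least one run (r >= 1)",
             "robustclust_validation_error")
  ok <- vapply(runs, inherits, logical(1), what = "cluster_run")
  if (!all(ok))
    rc_error("all elements of `runs` must be cluster_run objects",
             "robustclust_validation_error")
  structure(
    list(algorithm = as.character(algorithm),
         dataset = as.character(dataset),
         runs = runs),
    class = "run_collection")
}

#' Item universe of a run collection
#'
#' The union of all items appearing in any run, sorted.
#'
#' @param runs A `run_collection`.
#' @return Character vector of item identifiers.
#' @export
run_universe <- function(runs) {
  stopifnot(inherits(runs, "run_collection"))
  sort(unique(unlist(lapply(runs$runs, function(r)
    unlist(r$clusters, use.names = FALSE)), use.names = FALSE)))
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf("<cluster_run '%s' (setting %s): %d clusters, %d items>\n",
              x$run_id, x$setting_value, length(x$clusters),
              length(unlist(x$clusters, use.names = FALSE))))
  invisible(x)
}

#' @export
print.run_collection <- function(x, ...) {
  cat(sprintf("<run_collection: %s on %s, r = %d runs, %d items>\n",
              x$algorithm, x$dataset, length(x$runs),
              length(run_universe(x))))
  invisible(x)
}
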