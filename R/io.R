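# Readers and writers for the plain-text interchange formats:
#   membership file : TSV `cluster_id<TAB>item_id`, '#' comments ignored
#   manifest        : TSV `run_id<TAB>setting_value<TAB>filename`
#   expression      : TSV, header row = sample IDs, first column = gene IDs

read_tsv_lines <- function(path) {
  if (!file.exists(path))
    rc_error(sprintf("file not found: '%s'", path), "robustclust_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

parse_membership <- function(path, run_id) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L)
    rc_error(sprintf("membership file for run '%s' is empty: '%s'",
                     run_id, path), "robustclust_io_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    rc_error(sprintf(
      "run '%s': line %d of '%s' does not have exactly two tab-separated fields",
      run_id, bad[1L], path), "robustclust_io_error")
  data.frame(cluster_id = vapply(parts, `[`, "", 1L),
             item_id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

membership_to_run <- function(df, run_id, setting_value) {
  clusters <- split(df$item_id, factor(df$cluster_id, levels = unique(df$cluster_id)))
  cluster_run(clusters, run_id = run_id, setting_value = setting_value)
}

#' Read a run collection from a manifest
#'
#' The manifest is a TSV with columns `run_id`, `setting_value`, `filename`
#' (no header; `#` comment lines ignored). Filenames are resolved relative
#' to the manifest's directory. Each referenced membership file is validated
#' on load: an item assigned to two clusters within one run is rejected with
#' an error naming the run and the item.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param algorithm,dataset Labels stored on the returned collection.
#' @return A [run_collection()] with runs in manifest order.
#' @export
read_run_collection <- function(manifest_path, algorithm = "unknown",
                                dataset = "unknown") {
  lines <- read_tsv_lines(manifest_path)
  if (length(lines) == 0L)
    rc_error(sprintf("manifest '%s' lists no runs", manifest_path),
             "robustclust_io_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    rc_error(sprintf(
      "manifest '%s': each line must be run_id<TAB>setting_value<TAB>filename",
      manifest_path), "robustclust_io_error")
  dir <- dirname(manifest_path)
  runs <- lapply(parts, function(p) {
    path <- file.path(dir, p[3L])
    membership_to_run(parse_membership(path, p[1L]), p[1L], p[2L])
  })
  run_collection(runs, algorithm = algorithm, dataset = dataset)
}

check_tsv_safe <- function(ids, what) {
  bad <- grepl("[\t\n\r]", ids)
  if (any(bad))
    rc_error(sprintf("%s %s contains a tab or newline; not representable in the TSV dialect",
                     what, sQuote(ids[bad][1L])),
             "robustclust_validation_error")
  invisible(TRUE)
}

#' Write a clustering run as a membership file
#'
#' One line per item, `cluster_id<TAB>item_id`. Reading the file back yields
#' a run with identical pair structure (cluster identifiers may be
#' relabeled, which robustness is insensitive to).
#'
#' @param run A [cluster_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "cluster_run"))
  check_tsv_safe(unlist(run$clusters, use.names = FALSE), "item ID")
  check_tsv_safe(names(run$clusters), "cluster ID")
  lines <- unlist(Map(function(id, items) paste(id, items, sep = "\t"),
                      names(run$clusters), run$clusters), use.names = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a run collection as membership files plus a manifest
#'
#' @param runs A [run_collection()].
#' @param dir Output directory (created if missing).
#' @param manifest Manifest filename within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_run_collection <- function(runs, dir, manifest = "manifest.tsv") {
  stopifnot(inherits(runs, "run_collection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("run_%03d.tsv", seq_along(runs$runs))
  for (i in seq_along(runs$runs))
    write_run(runs$runs[[i]], file.path(dir, files[i]))
  lines <- vapply(seq_along(runs$runs), function(i) {
    r <- runs$runs[[i]]
    paste(r$run_id, r$setting_value, files[i], sep = "\t")
  }, "")
  mpath <- file.path(dir, manifest)
  writeLines(c("# run_id\tsetting_value\tfilename", lines), mpath)
  invisible(mpath)
}

#' Read a gene-expression matrix
#'
#' Expects a TSV whose header row holds sample identifiers and whose first
#' column holds gene identifiers; values are expression measurements,
#' conventionally on the log2 scale. Rows containing missing values are
#' dropped (with a message). Genes with zero variance are loaded but flagged
#' in the `constant_genes` attribute, since their Pearson correlation with
#' anything is undefined.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix (genes x samples) with `rownames` = gene IDs,
#'   `colnames` = sample IDs and attribute `constant_genes`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    rc_error(sprintf("file not found: '%s'", path), "robustclust_io_error")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L)
    rc_error(sprintf("'%s' has no sample columns", path), "robustclust_io_error")
  genes <- df[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L)
    rc_error(sprintf("duplicate gene ID(s) in '%s': %s", path,
                     paste(sQuote(dup), collapse = ", ")),
             "robustclust_io_error")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    rc_error(sprintf("duplicate sample ID(s) in '%s'", path),
             "robustclust_io_error")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & toupper(vals) != "NA" & nzchar(vals),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    rc_error(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in '%s'",
                     vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                     samples[bad[1L, 2L]], path),
             "robustclust_io_error")
  rownames(num) <- genes
  colnames(num) <- samples
  drop <- apply(num, 1L, anyNA)
  if (any(drop)) {
    message(sprintf("read_expression: dropping %d gene(s) with missing values",
                    sum(drop)))
    num <- num[!drop, , drop = FALSE]
  }
  const <- rownames(num)[apply(num, 1L, function(x) max(x) == min(x))]
  attr(num, "constant_genes") <- const
  num
}

#' Write an expression matrix in the TSV dialect read by [read_expression()]
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param id_column Header of the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest an externally produced clustering run
#'
#' Reads a membership file written by an external tool (e.g. a WGCNA module
#' assignment or a CLICK solution exported to the two-column TSV dialect)
#' and validates it as a [cluster_run()]. A pseudo-cluster of unassigned
#' items (such as WGCNA's grey module) can be excluded by label. Clusters
#' sharing items are rejected, with one documented exception: when
#' `allow_shared_singleton = TRUE` (the nearest-neighbor-network convention,
#' where two clusters may share a single articulation item), an item found
#' in exactly two clusters is assigned to the first of them for pair
#' counting.
#'
#' @param path Membership TSV.
#' @param algorithm External algorithm name used to tag the run.
#' @param run_id,setting_value Run labels.
#' @param exclude_labels Cluster IDs to drop before validation.
#' @param allow_shared_singleton Permit one shared item between two clusters.
#' @return A [cluster_run()].
#' @export
ingest_external_run <- function(path, algorithm, run_id = basename(path),
                                setting_value = NA_character_,
                                exclude_labels = character(),
                                allow_shared_singleton = FALSE) {
  df <- parse_membership(path, run_id)
  df <- df[!(df$cluster_id %in% exclude_labels), , drop = FALSE]
  if (nrow(df) == 0L)
    rc_error(sprintf("run '%s': no clusters remain after excluding labels",
                     run_id), "robustclust_io_error")
  if (allow_shared_singleton) {
    tab <- table(df$item_id)
    shared <- names(tab)[tab == 2L]
    over <- names(tab)[tab > 2L]
    if (length(over) > 0L)
      rc_error(sprintf("run '%s': item %s appears in more than two clusters",
                       run_id, sQuote(over[1L])),
               "robustclust_validation_error")
    # keep the first occurrence of each doubly-assigned item
    drop <- duplicated(df$item_id) & df$item_id %in% shared
    df <- df[!drop, , drop = FALSE]
  }
  run <- membership_to_run(df, run_id, setting_value)
  attr(run, "algorithm") <- algorithm
  run
}

#' Write a robustness report table
#'
#' One row per (algorithm, dataset) cell with columns `algorithm`,
#' `dataset`, `r`, `t`, `d`, `R`.
#'
#' @param report A data.frame as produced by [robustness_report()]
#'   (`$table`), or a single `robustness_result` plus `algorithm`/`dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_robustness_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  need <- c("algorithm", "dataset", "r", "t", "d", "R")
  if (!all(need %in% colnames(report)))
    rc_error(sprintf("report must have columns: %s",
                     paste(need, collapse = ", ")),
             "robustclust_validation_error")
  write.table(report[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write per-pair robustness scores
#'
#' TSV with columns `item_a`, `item_b`, `count`, `score`.
#'
#' @param result A `robustness_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(result, path) {
  stopifnot(inherits(result, "robustness_result"))
  write.table(as.data.frame(result$pair_scores), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
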