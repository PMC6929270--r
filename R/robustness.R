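# Pair co-occurrence counting and the robustness metric R = t / (d * r).

run_pairs_dt <- function(run) {
  # all unordered co-clustered pairs of one run; clusters are disjoint so no
  # pair can arise twice within a run
  big <- run$clusters[lengths(run$clusters) >= 2L]
  if (length(big) == 0L)
    return(data.table::data.table(item_a = character(), item_b = character()))
  pieces <- lapply(big, function(cl) {
    cl <- sort(cl)
    m <- combn(cl, 2L)
    data.table::data.table(item_a = m[1L, ], item_b = m[2L, ])
  })
  data.table::rbindlist(pieces)
}

#' Count pair co-occurrences across clustering runs
#'
#' For every unordered pair of items that shares a cluster in at least one
#' run, counts the number of runs in which the pair is co-clustered. Pairs
#' never co-clustered are absent from the table. The table carries the two
#' aggregate quantities the robustness metric is built from: `t`, the total
#' number of (not necessarily distinct) co-clustered pairs summed over all
#' runs, and `d`, the number of distinct pairs ever co-clustered.
#'
#' @param runs A [run_collection()].
#' @return An object of class `pair_table`: a list with elements
#'   `counts` (a `data.table` with columns `item_a`, `item_b`, `count`,
#'   sorted by pair), `t`, `d` and `r`.
#' @examples
#' rc <- run_collection(list(
#'   cluster_run(list(c("A","B","C","D"), c("E","F")), "run1"),
#'   cluster_run(list(c("A","B"), c("C","D"), c("E","F")), "run2"),
#'   cluster_run(list(c("A","B"), c("C","E"), c("D","F")), "run3")))
#' pt <- count_pairs(rc)
#' pt$t  # 13
#' pt$d  # 9
#' @export
count_pairs <- function(runs) {
  stopifnot(inherits(runs, "run_collection"))
  r <- length(runs$runs)
  all <- data.table::rbindlist(lapply(runs$runs, run_pairs_dt))
  item_a <- item_b <- NULL # NSE notes
  if (nrow(all) == 0L) {
    counts <- data.table::data.table(item_a = character(),
                                     item_b = character(),
                                     count = integer())
  } else {
    counts <- all[, list(count = .N), by = list(item_a, item_b)]
    data.table::setkey(counts, item_a, item_b)
  }
  structure(list(counts = counts[],
                 t = sum(counts$count),
                 d = nrow(counts),
                 r = r),
            class = "pair_table")
}

#' Robustness of a clustering algorithm over a setting sweep
#'
#' Computes `R = t / (d * r)`: the proportion of runs in which a pair of
#' items appears together in some cluster, given that the pair is
#' co-clustered in at least one run, averaged over all such pairs. `t` is the
#' total number of co-clustered pairs summed over runs, `d` the number of
#' distinct ever-co-clustered pairs, and `r` the number of runs. `R` lies in
#' (0, 1]; higher values mean the algorithm keeps pairs together as the
#' swept setting changes.
#'
#' The exact integers `t`, `d` and `r` are retained alongside `R`, so the
#' value can be re-rendered at any precision; [format()] and [print()]
#' methods show `R` to 3 decimal places and per-pair scores to 4, the
#' conventional reporting precision for this metric.
#'
#' @param runs A [run_collection()], or a `pair_table` from [count_pairs()].
#' @return An object of class `robustness_result`: list with `R`, `t`, `d`,
#'   `r`, and `pair_scores` (a `data.table` with columns `item_a`, `item_b`,
#'   `count`, `score` where `score = count / r`).
#' @examples
#' rc <- run_collection(list(
#'   cluster_run(list(c("A","B","C","D"), c("E","F")), "run1"),
#'   cluster_run(list(c("A","B"), c("C","D"), c("E","F")), "run2"),
#'   cluster_run(list(c("A","B"), c("C","E"), c("D","F")), "run3")))
#' res <- robustness(rc)
#' round(res$R, 3)  # 0.481
#' @export
robustness <- function(runs) {
  pt <- if (inherits(runs, "pair_table")) runs else count_pairs(runs)
  if (pt$d == 0L)
    rc_error(paste0(
      "robustness is undefined: no pair of items is co-clustered in any ",
      "run (all clusters are singletons)"),
      "robustclust_undefined_robustness")
  scores <- data.table::copy(pt$counts)
  scores[, "score" := scores$count / pt$r]
  structure(list(R = pt$t / (pt$d * pt$r),
                 t = pt$t, d = pt$d, r = pt$r,
                 pair_scores = scores[]),
            class = "robustness_result")
}

#' Robustness score of a single item pair
#'
#' The fraction of runs in which the two items share a cluster. A pair that
#' is never co-clustered scores 0 (such pairs do not enter the aggregate
#' `R`, which averages only over ever-co-clustered pairs).
#'
#' @param pair Character vector of two item identifiers.
#' @param runs A [run_collection()].
#' @return A number in \[0, 1\].
#' @export
pair_score <- function(pair, runs) {
  stopifnot(inherits(runs, "run_collection"))
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L])
    rc_error("`pair` must be two distinct item identifiers",
             "robustclust_validation_error")
  uni <- run_universe(runs)
  missing <- setdiff(pair, uni)
  if (length(missing) > 0L)
    rc_error(sprintf("item(s) %s not present in any run",
                     paste(sQuote(missing), collapse = ", ")),
             "robustclust_key_error")
  hits <- vapply(runs$runs, function(run) {
    any(vapply(run$clusters, function(cl) all(pair %in% cl), logical(1)))
  }, logical(1))
  sum(hits) / length(runs$runs)
}

#' Summarize robustness across datasets
#'
#' Aggregates per-dataset robustness values for one algorithm into their
#' mean and coefficient of variation (CV = standard deviation / mean, using
#' the sample standard deviation with the n - 1 denominator). A low CV
#' indicates that the algorithm's robustness is stable across datasets.
#'
#' @param results A named list mapping dataset name to a
#'   `robustness_result` (or directly to a numeric `R` value).
#' @return An object of class `robustness_summary`: list with `per_dataset`
#'   (named numeric vector of R values), `mean_R`, `cv` (`NA` when fewer
#'   than two datasets are available), `sd_convention` (`"sample"`).
#' @export
summarize_robustness <- function(results) {
  if (length(results) < 1L)
    rc_error("at least one dataset result is required",
             "robustclust_validation_error")
  vals <- vapply(results, function(x) {
    if (inherits(x, "robustness_result")) x$R else as.numeric(x)
  }, numeric(1))
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    rc_error("`results` must be named by dataset",
             "robustclust_validation_error")
  m <- mean(vals)
  cv <- if (length(vals) >= 2L && m > 0) sd(vals) / m else NA_real_
  structure(list(per_dataset = vals, mean_R = m, cv = cv,
                 sd_convention = "sample"),
            class = "robustness_summary")
}

#' @export
format.robustness_result <- function(x, digits = 3L, ...) {
  sprintf("R = %s (t = %d, d = %d, r = %d)",
          formatC(x$R, format = "f", digits = digits), x$t, x$d, x$r)
}

#' @export
print.robustness_result <- function(x, digits = 3L, max_pairs = 10L, ...) {
  cat("<robustness_result> ", format(x, digits = digits), "\n", sep = "")
  ps <- x$pair_scores
  shown <- utils::head(ps, max_pairs)
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  (%s,%s): %d/%d = %s\n", shown$item_a[i], shown$item_b[i],
                shown$count[i], x$r,
                formatC(shown$score[i], format = "f", digits = 4L)))
  if (nrow(ps) > max_pairs)
    cat(sprintf("  ... %d more pairs\n", nrow(ps) - max_pairs))
  invisible(x)
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("<robustness_summary> mean R = %.3f, CV = %s over %d dataset(s)\n",
              x$mean_R,
              if (is.na(x$cv)) "NA" else sprintf("%.3f", x$cv),
              length(x$per_dataset)))
  invisible(x)
}
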