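test_that("pair counting reproduces the worked three-run example", {
  pt <- count_pairs(fig_runs())
  expect_s3_class(pt, "pair_table")
  expect_equal(pt$t, 13L)
  expect_equal(pt$d, 9L)
  expect_equal(pt$r, 3L)
  expect_equal(pair_count(pt, "A", "B"), 3L)
  expect_equal(pair_count(pt, "C", "D"), 2L)
  expect_equal(pair_count(pt, "E", "F"), 2L)
  for (p in list(c("A","C"), c("A","D"), c("B","C"), c("B","D"),
                 c("C","E"), c("D","F")))
    expect_equal(pair_count(pt, p[1], p[2]), 1L)
  expect_equal(pair_count(pt, "A", "E"), 0L)
})

test_that("robustness equals t/(d*r) and matches the printed value", {
  res <- robustness(fig_runs())
  expect_equal(res$R, 13 / 27)
  expect_equal(round(res$R, 3), 0.481)
  expect_equal(res$R, mean(res$pair_scores$score))
  expect_match(format(res), "R = 0.481")
})

test_that("pair scores are co-occurrence fractions", {
  rc <- fig_runs()
  expect_equal(pair_score(c("A", "B"), rc), 1)
  expect_equal(pair_score(c("C", "D"), rc), 2 / 3)
  # a never-co-clustered pair scores 0 and is absent from pair_scores
  expect_equal(pair_score(c("A", "E"), rc), 0)
  ps <- robustness(rc)$pair_scores
  expect_false(any(ps$item_a == "A" & ps$item_b == "E"))
  # a pair together in 17 of 23 runs scores 17/23 = 0.7391
  runs23 <- lapply(1:23, function(i) {
    cl <- if (i <= 17) list(c("A", "B"), "C") else list("A", c("B", "C"))
    cluster_run(cl, sprintf("r%d", i))
  })
  expect_equal(round(pair_score(c("A", "B"), run_collection(runs23)), 4),
               0.7391)
  expect_error(pair_score(c("A", "Z"), rc), "Z",
               class = "robustclust_key_error")
})

test_that("degenerate inputs are rejected, not silently numeric", {
  singletons <- run_collection(list(
    cluster_run(list("A", "B", "C"), "r1")))
  pt <- count_pairs(singletons)
  expect_equal(pt$t, 0L)
  expect_equal(pt$d, 0L)
  expect_error(robustness(singletons), "undefined",
               class = "robustclust_undefined_robustness")
  expect_error(
    cluster_run(list(c("A", "B"), c("B", "C")), "bad_run"),
    "bad_run.*B", class = "robustclust_validation_error")
})

test_that("identical runs give R = 1 with every count equal to r", {
  run <- cluster_run(list(c("A", "B", "C"), c("D", "E")), "r")
  rc <- run_collection(lapply(1:4, function(i) run))
  res <- robustness(rc)
  expect_equal(res$R, 1)
  expect_true(all(res$pair_scores$count == 4L))
})

test_that("robustness matches the brute-force all-pairs oracle", {
  set.seed(101)
  for (i in 1:40) {
    rc <- random_run_collection(sample(3:10, 1), sample(1:5, 1))
    ours <- tryCatch(robustness(rc), robustclust_undefined_robustness =
                       function(e) NULL)
    orc <- oracle_robustness(rc)
    if (is.null(ours)) {
      expect_equal(orc$d, 0L)
    } else {
      expect_equal(ours$R, orc$R)
      expect_equal(ours$t, orc$t)
      expect_equal(ours$d, orc$d)
    }
  }
})

test_that("R is invariant under item relabeling and run reordering", {
  set.seed(7)
  for (i in 1:10) {
    rc <- random_run_collection(8, 4)
    r0 <- robustness(rc)$R
    perm <- sample(run_universe(rc))
    names(perm) <- run_universe(rc)
    relabeled <- run_collection(lapply(sample(rc$runs), function(run) {
      cluster_run(lapply(run$clusters, function(cl) unname(perm[cl])),
                  run$run_id)
    }))
    expect_equal(robustness(relabeled)$R, r0)
  }
})

test_that("coarsening a run never decreases t or any existing pair count", {
  set.seed(13)
  for (i in 1:10) {
    rc <- random_run_collection(8, 3, k = 4)
    run <- rc$runs[[1]]
    if (length(run$clusters) < 2) next
    merged <- c(list(unlist(run$clusters[1:2], use.names = FALSE)),
                run$clusters[-(1:2)])
    rc2 <- run_collection(c(list(cluster_run(merged, "merged")), rc$runs[-1]))
    pt1 <- count_pairs(rc); pt2 <- count_pairs(rc2)
    expect_gte(pt2$t, pt1$t)
    for (j in seq_len(pt1$d))
      expect_gte(pair_count(pt2, pt1$counts$item_a[j], pt1$counts$item_b[j]),
                 pt1$counts$count[j])
  }
})

test_that("bounds: 0 < R <= 1, with R = 1 only for all-run co-clustering", {
  set.seed(19)
  for (i in 1:20) {
    rc <- random_run_collection(sample(4:9, 1), sample(2:5, 1))
    res <- tryCatch(robustness(rc), robustclust_undefined_robustness =
                      function(e) NULL)
    if (is.null(res)) next
    expect_gt(res$R, 0)
    expect_lte(res$R, 1)
    expect_equal(res$R == 1, all(res$pair_scores$count == res$r))
  }
})

test_that("cross-dataset summaries use mean and sample-sd CV", {
  s <- summarize_robustness(list(d1 = 0.5, d2 = 0.5))
  expect_equal(s$mean_R, 0.5)
  expect_equal(s$cv, 0)
  s2 <- summarize_robustness(list(d1 = 0.4, d2 = 0.6))
  expect_equal(s2$mean_R, 0.5)
  expect_equal(s2$cv, sd(c(0.4, 0.6)) / 0.5)
  expect_equal(round(s2$cv, 4), 0.2828)
  # single dataset: mean defined, cv absent (not zero)
  s3 <- summarize_robustness(list(d1 = 1.0))
  expect_equal(s3$mean_R, 1.0)
  expect_true(is.na(s3$cv))
  # robustness_result inputs are accepted directly
  s4 <- summarize_robustness(list(toy = robustness(fig_runs())))
  expect_equal(s4$mean_R, 13 / 27)
})
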