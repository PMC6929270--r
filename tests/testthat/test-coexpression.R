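toy_expr <- function(n = 4, s = 10, seed = 3) {
  set.seed(seed)
  matrix(rnorm(n * s), n, s,
         dimnames = list(paste0("g", seq_len(n)), paste0("smp", seq_len(s))))
}

test_that("correlation matrix has textbook Pearson behavior", {
  expr <- toy_expr(3, 12)
  dup <- rbind(expr, g4 = expr["g1", ], g5 = -expr["g2", ])
  cc <- correlation_matrix(dup)
  expect_equal(unname(cc["g1", "g4"]), 1)
  expect_equal(unname(cc["g2", "g5"]), -1)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  # two independent standard-normal genes at n = 1e4: |rho_hat| < 0.05
  set.seed(42)
  big <- matrix(rnorm(2e4), 2, dimnames = list(c("a", "b"), NULL))
  colnames(big) <- paste0("s", 1:1e4)
  expect_lt(abs(correlation_matrix(big)["a", "b"]), 0.05)
  # constant gene named in the error
  cexpr <- rbind(expr, flat = rep(2, 12))
  expect_error(correlation_matrix(cexpr), "flat",
               class = "robustclust_validation_error")
  expect_error(correlation_matrix(expr[, 1:2, drop = FALSE]),
               class = "robustclust_validation_error")
})

test_that("correlation agrees with a two-pass implementation to 1e-10", {
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(11)
  for (trial in 1:5) {
    expr <- matrix(rnorm(200), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
    cc <- correlation_matrix(expr)
    for (i in 1:19) for (j in (i + 1):20)
      expect_equal(cc[i, j], two_pass(expr[i, ], expr[j, ]),
                   tolerance = 1e-10)
  }
})

test_that("hard thresholding keeps exactly the edges at or above tau", {
  corr <- matrix(c(1, 0.96, 0.91, 0.2,
                   0.96, 1, 0.85, 0.1,
                   0.91, 0.85, 1, -0.4,
                   0.2, 0.1, -0.4, 1), 4, 4,
                 dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  cg <- threshold_graph(corr, 0.9)
  el <- igraph::as_data_frame(cg$graph)
  expect_equal(nrow(el), 2L)
  expect_setequal(paste(el$from, el$to), c("g1 g2", "g1 g3"))
  expect_equal(igraph::vcount(cg$graph), 4L)   # isolated vertices kept
  # boundary thresholds
  expect_equal(igraph::ecount(threshold_graph(corr, 1.0)$graph), 0L)
  expect_equal(igraph::ecount(threshold_graph(corr, -1.0)$graph), 6L)
  # absolute mode admits strong negative correlations
  expect_equal(igraph::ecount(threshold_graph(corr, 0.4, absolute = TRUE)$graph),
               4L)  # |-0.4| >= 0.4 admits the negative edge too
  expect_error(threshold_graph(corr, 1.5),
               class = "robustclust_validation_error")
})

test_that("edge sets are monotone decreasing in tau", {
  set.seed(21)
  expr <- toy_expr(10, 15)
  corr <- correlation_matrix(expr)
  taus <- c(-0.5, 0, 0.3, 0.6, 0.9)
  edge_key <- function(cg) {
    el <- igraph::as_data_frame(cg$graph)
    paste(pmin(el$from, el$to), pmax(el$from, el$to))
  }
  prev <- NULL
  for (tau in rev(taus)) {       # from tightest to loosest
    cur <- edge_key(threshold_graph(corr, tau))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("suggested threshold separates planted modules from background", {
  cfg <- synthetic_config(n_modules = 2, module_sizes = 20L,
                          n_background = 20L, n_samples = 40L,
                          intra_module_corr = 0.95, background_corr = 0.3,
                          seed = 11)
  corr <- correlation_matrix(generate_expression(cfg)$expr)
  st <- suggest_threshold(corr, seq(0.05, 0.95, by = 0.05))
  expect_gt(st$tau, 0.3)
  expect_lt(st$tau, 0.95)
  dg <- st$diagnostics
  expect_equal(nrow(dg), 19L)
  expect_true(all(diff(dg$n_edges) <= 0))       # fewer edges as tau rises
  expect_true(all(diff(dg$lambda_max) <= 1e-9)) # leading eigenvalue declines
  expect_true(all(dg$tau >= 0 & dg$tau <= 1))
})

test_that("degenerate and invalid threshold suggestions are handled", {
  corr <- matrix(0.5, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(corr) <- 1
  # identical weights: eigenvalue collapses just above w, shoulder = largest
  # candidate at or below w
  st <- suggest_threshold(corr, c(0.2, 0.4, 0.6))
  expect_equal(st$tau, 0.4)
  expect_error(suggest_threshold(corr, c(0.2, 0.4)),
               class = "robustclust_validation_error")
  expect_error(suggest_threshold(corr, c(0.5, 0.4, 0.3)),
               class = "robustclust_validation_error")
})

test_that("edge lists serialize with weights", {
  corr <- correlation_matrix(toy_expr(5, 12))
  cg <- threshold_graph(corr, -1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(cg, path)
  el <- read.delim(path)
  expect_equal(colnames(el), c("gene_a", "gene_b", "weight"))
  expect_equal(nrow(el), 10L)
  expect_true(all(abs(el$weight) <= 1))
})
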