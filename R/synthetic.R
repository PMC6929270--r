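# Synthetic module-structured expression data with known ground truth.

#' Configuration for the synthetic expression generator
#'
#' Describes a latent-factor model of module-structured gene expression:
#' each planted module shares one latent sample profile, each member gene is
#' that profile plus independent Gaussian noise, and background genes carry
#' at most a weak common factor. The loading on the latent profile is
#' derived in closed form so that the expected Pearson correlation between
#' two genes of the same module equals `intra_module_corr` for any
#' `noise_sd` (the noise level only sets the absolute scale of variation).
#'
#' Defaults describe a well-separated two-module design: 2 modules of 20
#' genes, 50 background genes, 40 samples, intra-module correlation 0.9
#' against a background correlation of 0.1 -- a caricature of the strong
#' co-expression structure that thresholded microarray correlation networks
#' exhibit.
#'
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector of genes per module (recycled to
#'   `n_modules` if scalar).
#' @param n_background Number of background genes.
#' @param n_samples Number of samples (columns).
#' @param intra_module_corr Target Pearson correlation between genes of the
#'   same module, in (0, 1).
#' @param background_corr Target correlation among background genes, in
#'   \[0, 1) and below `intra_module_corr`.
#' @param noise_sd Standard deviation of per-gene noise (> 0), on the log2
#'   expression scale.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_modules = 2L, module_sizes = 20L,
                             n_background = 50L, n_samples = 40L,
                             intra_module_corr = 0.9, background_corr = 0.1,
                             noise_sd = 1, seed = 1L) {
  if (length(module_sizes) == 1L)
    module_sizes <- rep(module_sizes, n_modules)
  if (length(module_sizes) != n_modules)
    rc_error("`module_sizes` must have one entry per module",
             "robustclust_validation_error")
  if (intra_module_corr >= 1 || intra_module_corr <= 0)
    rc_error("`intra_module_corr` must lie strictly inside (0, 1)",
             "robustclust_validation_error")
  if (background_corr < 0 || background_corr >= 1)
    rc_error("`background_corr` must lie in [0, 1)",
             "robustclust_validation_error")
  if (intra_module_corr <= background_corr)
    rc_error("`intra_module_corr` must exceed `background_corr`",
             "robustclust_validation_error")
  if (noise_sd <= 0)
    rc_error("`noise_sd` must be positive", "robustclust_validation_error")
  structure(list(n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 n_background = as.integer(n_background),
                 n_samples = as.integer(n_samples),
                 intra_module_corr = intra_module_corr,
                 background_corr = background_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# loading that makes cor(gene_i, gene_j) = rho when both load on a shared
# N(0,1) latent factor and carry independent N(0, sd^2) noise:
# lambda^2 / (lambda^2 + sd^2) = rho  =>  lambda = sd * sqrt(rho / (1 - rho))
latent_loading <- function(rho, noise_sd) {
  if (rho == 0) return(0)
  noise_sd * sqrt(rho / (1 - rho))
}

#' Generate a module-structured expression matrix with ground truth
#'
#' Draws a log2-scale expression matrix under the latent-factor model of
#' [synthetic_config()]: module genes = per-gene baseline + loading x shared
#' module profile + noise; background genes analogously on a weak global
#' factor (independent when `background_corr = 0`). Baselines are uniform
#' on \[6, 12\], mimicking log2 microarray intensities.
#'
#' @param config A [synthetic_config()].
#' @return List with `expr` (matrix, genes x samples), `labels` (named
#'   character vector: `"module<i>"` or `"background"` per gene) and
#'   `config`.
#' @export
generate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  n_genes <- sum(config$module_sizes) + config$n_background
  s <- config$n_samples
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  labels <- rep("background", n_genes)
  expr <- matrix(0, n_genes, s,
                 dimnames = list(gene_ids, sprintf("sample%03d", seq_len(s))))
  lam_m <- latent_loading(config$intra_module_corr, config$noise_sd)
  lam_b <- latent_loading(config$background_corr, config$noise_sd)
  baselines <- runif(n_genes, 6, 12)
  row <- 1L
  for (m in seq_len(config$n_modules)) {
    profile <- rnorm(s)
    for (i in seq_len(config$module_sizes[m])) {
      expr[row, ] <- baselines[row] + lam_m * profile +
        rnorm(s, sd = config$noise_sd)
      labels[row] <- sprintf("module%d", m)
      row <- row + 1L
    }
  }
  bg_profile <- rnorm(s)
  while (row <= n_genes) {
    expr[row, ] <- baselines[row] + lam_b * bg_profile +
      rnorm(s, sd = config$noise_sd)
    row <- row + 1L
  }
  names(labels) <- gene_ids
  list(expr = expr, labels = labels, config = config)
}

#' Generate a thresholded co-expression graph with ground truth
#'
#' [generate_expression()] followed by [correlation_matrix()] and
#' [threshold_graph()] at `tau`. With `tau` placed between the background
#' and intra-module correlations of a well-separated config, planted
#' modules appear as near-cliques and background genes are mostly isolated.
#'
#' @param config A [synthetic_config()].
#' @param tau Hard threshold in \[-1, 1\].
#' @return List with `graph` (a `correlation_graph`), `labels`, `expr`,
#'   `config`.
#' @export
generate_graph <- function(config = synthetic_config(), tau = 0.7) {
  sim <- generate_expression(config)
  cg <- threshold_graph(correlation_matrix(sim$expr), tau)
  list(graph = cg, labels = sim$labels, expr = sim$expr, config = config)
}
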