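#' Simulate a tissue-labelled read-count matrix with planted enrichment
#'
#' Per-gene baseline log-means are Normal; a planted fraction of genes gets
#' a `log2(fold)` boost in one randomly chosen tissue each. Counts are
#' negative binomial with configurable dispersion around
#' `baseline * fold * library_scale`, with log-normal per-sample library
#' scales. Fixed seeds reproduce the matrix bit-identically.
#'
#' @param g_genes Number of genes (default 2000).
#' @param n_tissues Number of tissues (default 50).
#' @param samples_per_tissue Samples per tissue (default 10).
#' @param planted_frac Fraction of genes with a planted enriched tissue
#'   (default 0.05; 0 disables planting).
#' @param fold Fold-change of planted genes in their enriched tissue
#'   (default 8).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param base_log_mean,base_log_sd Baseline log-mean distribution
#'   (defaults log(50) and 1).
#' @param libsize_log_sd SD of log library scale (default 0.3).
#' @param gene_ids Optional gene identifiers (default G0001...).
#' @param seed Integer seed.
#' @return List with `counts` (a `count_matrix`) and `truth` (data frame
#'   `gene`, `tissue` of planted enrichments, plus the baseline means as an
#'   attribute).
#' @export
simulate_expression <- function(g_genes = 2000, n_tissues = 50,
                                samples_per_tissue = 10,
                                planted_frac = 0.05, fold = 8,
                                dispersion = 0.1,
                                base_log_mean = log(50), base_log_sd = 1,
                                libsize_log_sd = 0.3,
                                gene_ids = NULL, seed = 1) {
  stopifnot(n_tissues >= 2, g_genes >= 2, samples_per_tissue >= 1)
  with_seed(seed, {
    genes <- gene_ids %||% sprintf("G%04d", seq_len(g_genes))
    stopifnot(length(genes) == g_genes)
    tissues <- sprintf("T%02d", seq_len(n_tissues))
    s_tissue <- rep(tissues, each = samples_per_tissue)
    samples <- sprintf("%s_S%02d", s_tissue, rep(seq_len(samples_per_tissue),
                                                 times = n_tissues))
    lambda <- exp(stats::rnorm(g_genes, base_log_mean, base_log_sd))
    n_planted <- round(planted_frac * g_genes)
    planted <- if (n_planted > 0 && fold != 1) {
      data.frame(gene = sample(genes, n_planted),
                 tissue = sample(tissues, n_planted, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), tissue = character(),
                 stringsAsFactors = FALSE)
    }
    lib <- exp(stats::rnorm(length(samples), 0, libsize_log_sd))
    fold_mat <- matrix(1, g_genes, length(samples),
                       dimnames = list(genes, samples))
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        fold_mat[planted$gene[i], s_tissue == planted$tissue[i]] <- fold
      }
    }
    mu <- lambda * fold_mat * rep(lib, each = g_genes)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     g_genes, length(samples), dimnames = dimnames(fold_mat))
    cm <- count_matrix(counts, stats::setNames(s_tissue, samples))
    attr(planted, "baseline_mean") <- stats::setNames(lambda, genes)
    attr(planted, "fold") <- fold
    list(counts = cm, truth = planted)
  })
}
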