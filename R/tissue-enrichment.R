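#' Construct a gene-by-sample count matrix with tissue labels
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param tissue_of Named character vector mapping every sample id to a
#'   tissue label.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, tissue_of) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  miss <- setdiff(colnames(counts), names(tissue_of))
  if (length(miss)) stop("samples without tissue label: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  structure(list(counts = counts,
                 tissue_of = tissue_of[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %d tissues\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$tissue_of))))
  invisible(x)
}

#' Read a count matrix and tissue map from TSV
#'
#' @param counts_path TSV with genes as rows; first column `gene_id`, header
#'   gives sample ids.
#' @param tissues_path Two-column TSV `sample`, `tissue`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(counts_path, tissues_path) {
  dt <- data.table::fread(counts_path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- genes
  tm <- data.table::fread(tissues_path, sep = "\t", header = TRUE)
  tissue_of <- stats::setNames(as.character(tm[[2]]), as.character(tm[[1]]))
  count_matrix(mat, tissue_of)
}

#' Filter lowly detected genes
#'
#' Retains genes with at least `min_count` reads in at least `min_frac` of
#' samples (both thresholds inclusive). By default the detection fraction is
#' taken globally over all samples; with `per_tissue = TRUE` a gene is kept
#' when it reaches the fraction within at least one tissue.
#'
#' @param m A `count_matrix`.
#' @param min_count Minimum read count (default 5).
#' @param min_frac Minimum fraction of samples (default 0.20).
#' @param per_tissue Evaluate the detection fraction within tissues instead
#'   of globally (default FALSE).
#' @return Filtered `count_matrix`.
#' @export
filter_genes <- function(m, min_count = 5, min_frac = 0.20,
                         per_tissue = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  detected <- m$counts >= min_count
  keep <- if (per_tissue) {
    Reduce(`|`, lapply(unique(m$tissue_of), function(t) {
      rowMeans(detected[, m$tissue_of == t, drop = FALSE]) >= min_frac
    }))
  } else {
    rowMeans(detected) >= min_frac
  }
  pqtlx_log("gene detection filter: kept %d / %d genes", sum(keep), length(keep),
            level = 2L)
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample scaling factors, computed with
#' edgeR (reference = sample whose 75th-percentile count over library size is
#' closest to the mean of that quantity; 30%/5% double trimming of the M/A
#' distributions; precision-weighted trimmed mean; factors rescaled to
#' geometric mean 1). Normalized expression downstream is
#' `count / (library_size * factor) * 1e6` (CPM-like).
#'
#' @param m A `count_matrix` with at least 2 samples and positive library
#'   sizes.
#' @return Named per-sample factor vector with geometric mean 1.
#' @export
tmm_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(colSums(m$counts) <= 0)) stop("sample(s) with zero library size")
  f <- edgeR::calcNormFactors(m$counts, method = "TMM")
  stats::setNames(f, colnames(m$counts))
}

# CPM-like normalized expression given TMM factors.
normalized_expression <- function(m, factors) {
  lib <- colSums(m$counts) * factors[colnames(m$counts)]
  sweep(m$counts, 2, lib, "/") * 1e6
}

#' Per-tissue median normalized expression
#'
#' @param m A `count_matrix`.
#' @param factors TMM factors from [tmm_factors()].
#' @return Gene-by-tissue matrix of median normalized expression.
#' @export
tissue_medians <- function(m, factors) {
  stopifnot(inherits(m, "count_matrix"))
  expr <- normalized_expression(m, factors)
  tiss <- unique(m$tissue_of)
  out <- matrix(NA_real_, nrow(expr), length(tiss),
                dimnames = list(rownames(expr), tiss))
  for (t in tiss) {
    cols <- which(m$tissue_of == t)
    if (length(cols) == 0L) stop("tissue with zero samples: ", t)
    out[, t] <- row_medians(expr[, cols, drop = FALSE])
  }
  out
}

# Row medians without extra dependencies.
row_medians <- function(x) apply(x, 1, stats::median)

#' Two-stage tissue-enrichment z-scores
#'
#' Stage 1 standardizes each tissue's median-expression distribution across
#' genes using the median and the scaled median absolute deviation
#' (constant 1.4826). Stage 2 standardizes each gene's stage-1 scores across
#' tissues with the same robust statistics; a tissue is flagged elevated for
#' a gene when its z-score strictly exceeds `z_threshold`. Tissues with
#' stage-1 MAD of 0 are excluded (error-level log); genes with stage-2 MAD
#' of 0 are excluded with the reason recorded.
#'
#' @param med Gene-by-tissue matrix from [tissue_medians()].
#' @param z_threshold Elevation threshold (default 2, strict).
#' @return Object of class `enrichment_matrix`: `median_expr`, `stage1`,
#'   `z`, `elevated` (logical), `excluded_genes` (data frame with reasons),
#'   `excluded_tissues`, `z_threshold`.
#' @export
enrichment_z <- function(med, z_threshold = 2) {
  med <- as.matrix(med)
  if (ncol(med) < 2L || nrow(med) < 2L) stop("need >= 2 tissues and >= 2 genes")
  t_med <- apply(med, 2, stats::median)
  t_mad <- apply(med, 2, stats::mad)        # 1.4826-scaled
  bad_t <- t_mad == 0 | !is.finite(t_mad)
  if (any(bad_t)) {
    pqtlx_log("ERROR-level: excluded %d tissue(s) with zero stage-1 MAD: %s",
              sum(bad_t), paste(colnames(med)[bad_t], collapse = ", "))
  }
  keep_t <- !bad_t
  if (sum(keep_t) < 2L) stop("fewer than 2 tissues with positive stage-1 MAD")
  s1 <- sweep(sweep(med[, keep_t, drop = FALSE], 2, t_med[keep_t], "-"),
              2, t_mad[keep_t], "/")
  g_med <- apply(s1, 1, stats::median)
  g_mad <- apply(s1, 1, stats::mad)
  bad_g <- g_mad == 0 | !is.finite(g_mad)
  z <- (s1 - g_med) / g_mad
  z[bad_g, ] <- NA_real_
  elevated <- !is.na(z) & z > z_threshold
  excluded <- data.frame(gene = rownames(med)[bad_g],
                         reason = rep("stage-2 MAD = 0", sum(bad_g)),
                         stringsAsFactors = FALSE)
  structure(list(median_expr = med, stage1 = s1, z = z, elevated = elevated,
                 excluded_genes = excluded,
                 excluded_tissues = colnames(med)[bad_t],
                 z_threshold = z_threshold),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d genes x %d tissues, %d excluded gene(s), %d elevated flag(s)\n",
              nrow(x$z), ncol(x$z), nrow(x$excluded_genes), sum(x$elevated)))
  invisible(x)
}

# Pearson chi-squared on a 2x2 table, no continuity correction; NA when a
# marginal is zero (statistic undefined).
pearson_chi2_2x2 <- function(tab, correct = FALSE) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Contrast elevated expression by colocalization group
#'
#' Per tissue, a 2x2 Pearson chi-squared test (df = 1, no continuity
#' correction) of elevated-expression status against group membership
#' (colocalized vs non-colocalized proteins). The statistic is recorded as
#' absent when a table marginal is zero.
#'
#' @param e An `enrichment_matrix`.
#' @param group_of Named character vector mapping gene ids to `"coloc"` or
#'   `"noncoloc"`; genes absent from the map or excluded from `e` are
#'   ignored.
#' @param correct Apply the Yates continuity correction (default FALSE,
#'   matching large-sample practice).
#' @return Data frame with one row per tissue: elevated/total counts per
#'   group, proportions, `chi2`, `p`, `direction` (which group has the
#'   larger elevated proportion), significance `stars`.
#' @export
contrast_by_group <- function(e, group_of, correct = FALSE) {
  stopifnot(inherits(e, "enrichment_matrix"))
  group_of <- group_of[!is.na(group_of)]
  if (!all(group_of %in% c("coloc", "noncoloc"))) {
    stop("group labels must be 'coloc' or 'noncoloc'")
  }
  genes <- intersect(rownames(e$z), names(group_of))
  genes <- setdiff(genes, e$excluded_genes$gene)
  if (length(unique(group_of[genes])) < 2L) {
    stop("both groups must be non-empty among scored genes")
  }
  grp <- group_of[genes]
  res <- lapply(colnames(e$z), function(t) {
    el <- e$elevated[genes, t]
    n_ec <- sum(el & grp == "coloc")
    n_tc <- sum(grp == "coloc")
    n_en <- sum(el & grp == "noncoloc")
    n_tn <- sum(grp == "noncoloc")
    tab <- matrix(c(n_ec, n_tc - n_ec, n_en, n_tn - n_en), 2, 2, byrow = TRUE)
    ct <- pearson_chi2_2x2(tab, correct = correct)
    pc <- n_ec / n_tc
    pn <- n_en / n_tn
    data.frame(tissue = t,
               n_elevated_coloc = n_ec, n_total_coloc = n_tc,
               n_elevated_noncoloc = n_en, n_total_noncoloc = n_tn,
               prop_coloc = pc, prop_noncoloc = pn,
               chi2 = ct$chi2, p = ct$p,
               direction = if (isTRUE(pc > pn)) "coloc"
                           else if (isTRUE(pn > pc)) "noncoloc" else "equal",
               stars = significance_stars(ct$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
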