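make_cm <- function(counts, tissues = NULL) {
  g <- nrow(counts); s <- ncol(counts)
  rownames(counts) <- sprintf("G%03d", seq_len(g))
  colnames(counts) <- sprintf("S%03d", seq_len(s))
  if (is.null(tissues)) tissues <- rep("T1", s)
  count_matrix(counts, setNames(tissues, colnames(counts)))
}

test_that("gene detection filter applies inclusive global thresholds", {
  counts <- rbind(
    c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0),   # exactly 20% at exactly 5: kept
    rep(4, 10),                        # never reaches 5: removed
    rep(0, 10),                        # all-zero: removed
    rep(100, 10))                      # clearly kept
  m <- filter_genes(make_cm(counts))
  expect_identical(rownames(m$counts), c("G001", "G004"))
  # per-tissue mode keeps a gene detected well in a single tissue
  cm2 <- make_cm(rbind(c(9, 9, 0, 0, 0, 0, 0, 0, 0, 0), rep(50, 10)),
                 tissues = rep(c("T1", "T2"), each = 5))
  expect_equal(nrow(filter_genes(cm2, min_frac = 0.4)$counts), 1L)
  expect_equal(nrow(filter_genes(cm2, min_frac = 0.4, per_tissue = TRUE)$counts), 2L)
})

test_that("TMM factors are 1 for identical samples and scale-invariant", {
  set.seed(5)
  base <- rpois(500, 60)
  m_id <- make_cm(cbind(base, base, base, base))
  f <- tmm_factors(m_id)
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-6)
  # uniform 3x scaling cancels in M-values
  m_sc <- make_cm(cbind(base, base * 3L, base, base))
  f_sc <- tmm_factors(m_sc)
  expect_equal(f_sc[[2]], f_sc[[1]], tolerance = 1e-6)
  # geometric mean is 1
  expect_equal(exp(mean(log(f_sc))), 1, tolerance = 1e-9)
})

test_that("TMM recovers planted composition bias", {
  set.seed(6)
  g <- 2000
  lam <- exp(rnorm(g, log(100), 1))
  up <- seq_len(g) <= g * 0.10          # 10% of genes 8-fold up in sample 2
  lam2 <- lam * ifelse(up, 8, 1)
  counts <- cbind(rpois(g, lam), rpois(g, lam2), rpois(g, lam), rpois(g, lam))
  m <- make_cm(counts)
  f <- tmm_factors(m)
  # truth implied by the generator: unbiased genes should have equal
  # normalized expression, so f2/f1 = (sum lam / sum lam2) up to Poisson noise
  truth <- sum(lam) / sum(lam2)
  expect_equal(f[[2]] / f[[1]], truth, tolerance = 0.05)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("filtering that removes nothing leaves TMM factors unchanged", {
  set.seed(7)
  counts <- matrix(rpois(400 * 6, 80), 400, 6)
  m <- make_cm(counts)
  expect_identical(tmm_factors(filter_genes(m)), tmm_factors(m))
})

test_that("tissue medians are per-tissue, robust and permutation-invariant", {
  counts <- rbind(c(1, 2, 100, 7, 7), c(3, 3, 3, 9, 9))
  m <- make_cm(counts, tissues = c("T1", "T1", "T1", "T2", "T2"))
  f <- setNames(rep(1, 5), colnames(m$counts))
  lib <- colSums(m$counts)
  med <- tissue_medians(m, f)
  # odd-count tissue takes the middle value (on the CPM scale)
  expect_equal(med["G001", "T1"], median(counts[1, 1:3] / lib[1:3] * 1e6))
  # single-sample-equivalent: T2 values identical so median equals them
  expect_equal(med["G002", "T2"], unname(9 / lib[4] * 1e6))
  # permuting samples within a tissue changes nothing
  perm <- m
  perm$counts <- perm$counts[, c(3, 1, 2, 5, 4)]
  perm$tissue_of <- m$tissue_of[c(3, 1, 2, 5, 4)]
  expect_equal(tissue_medians(perm, f[c(3, 1, 2, 5, 4)]), med)
})

test_that("two-stage z-scores: degenerate, affine and row-scaling properties", {
  # all genes identical across tissues (columns are copies): every stage-2
  # MAD is 0, all genes excluded, none elevated
  med <- matrix(rep(c(1, 5, 9, 20), 3), 4, 3,
                dimnames = list(paste0("G", 1:4), paste0("T", 1:3)))
  e <- enrichment_z(med)
  expect_equal(nrow(e$excluded_genes), 4L)
  expect_false(any(e$elevated))

  # affine rescaling of one tissue leaves its stage-1 scores unchanged
  set.seed(8)
  med2 <- matrix(exp(rnorm(200)), 50, 4,
                 dimnames = list(sprintf("G%02d", 1:50), paste0("T", 1:4)))
  e2 <- enrichment_z(med2)
  med3 <- med2
  med3[, 2] <- 3 * med3[, 2] + 7
  e3 <- enrichment_z(med3)
  expect_equal(e3$stage1[, 2], e2$stage1[, 2], tolerance = 1e-12)
  # non-excluded rows have median 0 and scaled MAD 1
  ok <- setdiff(rownames(med2), e2$excluded_genes$gene)
  expect_equal(unname(apply(e2$z[ok, ], 1, median)), rep(0, length(ok)),
               tolerance = 1e-9)
  expect_equal(unname(apply(e2$z[ok, ], 1, mad)), rep(1, length(ok)),
               tolerance = 1e-9)
})

test_that("a planted 10-fold single-tissue elevation is the only flag for its gene", {
  hits <- 0L
  clean <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    set.seed(900 + i)
    med <- matrix(exp(rnorm(100 * 10, log(50), 0.15)), 100, 10,
                  dimnames = list(sprintf("G%03d", 1:100), sprintf("T%02d", 1:10)))
    med["G001", "T03"] <- med["G001", "T03"] * 10
    e <- enrichment_z(med)
    if (isTRUE(e$z["G001", "T03"] > 2)) hits <- hits + 1L
    if (sum(e$elevated["G001", ]) == 1L) clean <- clean + 1L
  }
  expect_gte(hits / reps, 0.95)
  expect_gte(clean / reps, 0.95)
})

test_that("group contrasts reproduce the hand-computed chi-squared", {
  # table [[30,70],[10,90]]: expected counts 20/80, chi2 = 12.5 exactly
  z <- matrix(0, 200, 2, dimnames = list(sprintf("G%03d", 1:200),
                                         c("T1", "T2")))
  elevated <- matrix(FALSE, 200, 2, dimnames = dimnames(z))
  elevated[1:30, "T1"] <- TRUE          # coloc genes 1..100
  elevated[101:110, "T1"] <- TRUE       # noncoloc genes 101..200
  e <- structure(list(median_expr = z, stage1 = z, z = z, elevated = elevated,
                      excluded_genes = data.frame(gene = character(),
                                                  reason = character()),
                      excluded_tissues = character(), z_threshold = 2),
                 class = "enrichment_matrix")
  grp <- setNames(rep(c("coloc", "noncoloc"), each = 100), rownames(z))
  ct <- contrast_by_group(e, grp)
  t1 <- ct[ct$tissue == "T1", ]
  expect_equal(t1$chi2, 12.5, tolerance = 1e-12)
  # Yates correction shrinks the statistic when requested
  expect_lt(contrast_by_group(e, grp, correct = TRUE)[1, "chi2"], 12.5)
  expect_equal(t1$n_elevated_coloc, 30)
  expect_equal(t1$direction, "coloc")
  expect_identical(t1$stars, "***")
  # identical proportions: chi2 = 0, p = 1 is undefined here because T2 has a
  # zero "elevated" marginal -> recorded as absent
  expect_true(is.na(ct[ct$tissue == "T2", "chi2"]))
  # equal nonzero proportions give chi2 = 0, p = 1
  elevated[, "T2"] <- rep(c(TRUE, FALSE), 100)
  e$elevated <- elevated
  ct2 <- contrast_by_group(e, grp)
  expect_equal(ct2[ct2$tissue == "T2", "chi2"], 0, tolerance = 1e-12)
  expect_equal(ct2[ct2$tissue == "T2", "p"], 1, tolerance = 1e-12)
  # swapping group labels leaves chi2 and p unchanged
  grp_sw <- setNames(ifelse(grp == "coloc", "noncoloc", "coloc"), names(grp))
  ct3 <- contrast_by_group(e, grp_sw)
  expect_equal(ct3$chi2, ct2$chi2)
  expect_equal(ct3$p, ct2$p)
  # totals add up to the scored, labelled genes
  expect_equal(ct2$n_total_coloc + ct2$n_total_noncoloc, rep(200, 2))
})

test_that("counts round-trip through TSV with tissue labels", {
  sim <- simulate_expression(g_genes = 30, n_tissues = 3,
                             samples_per_tissue = 2, planted_frac = 0.1,
                             seed = 12)
  d <- withr::local_tempdir()
  cts <- data.frame(gene_id = rownames(sim$counts$counts), sim$counts$counts,
                    check.names = FALSE)
  data.table::fwrite(cts, file.path(d, "c.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample = names(sim$counts$tissue_of),
                                tissue = unname(sim$counts$tissue_of)),
                     file.path(d, "t.tsv"), sep = "\t")
  m <- read_counts(file.path(d, "c.tsv"), file.path(d, "t.tsv"))
  expect_equal(unname(m$counts), unname(sim$counts$counts))
  expect_identical(unname(m$tissue_of), unname(sim$counts$tissue_of))
})
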