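test_that("Wakefield ABF matches its closed form and limits", {
  # hand-evaluated: V = 0.01, z = 5, W = 0.0225
  expect_equal(wakefield_log_abf(0.5, 0.1, W = 0.0225), 8.0645, tolerance = 1e-3)
  # null effect leaves only the (non-positive) Occam factor
  expect_equal(wakefield_log_abf(0, 0.3, W = 0.0225),
               0.5 * log(0.09 / (0.09 + 0.0225)))
  expect_lte(wakefield_log_abf(0, 0.3), 0)
  # prior collapsing to the null gives no evidence either way
  expect_equal(wakefield_log_abf(0.5, 0.1, W = 0), 0)
  expect_error(wakefield_log_abf(0.5, -0.1), "positive")
  expect_error(wakefield_log_abf(Inf, 0.1), "finite")
})

test_that("no signals are detected when all |z| are sub-threshold", {
  set.seed(21)
  s <- make_stats(pos = 1:20, beta = rnorm(20, 0, 0.01), se = 0.01, n = 1000)
  expect_identical(detect_signals(s, identity_ld(s)), list())
})

test_that("single-causal loci yield one signal, identically for K = 1 and K = 10", {
  sc <- locus_scenario("SHARED_CONCORDANT", seed = 31)
  loc <- simulate_locus(sc)
  h <- harmonize_pair(apply_qc(filter_cis(loc$a)), apply_qc(filter_cis(loc$b)))
  ld <- compute_ld(loc$panel, keys = h$a$records[c("chrom", "pos", "a1", "a2")])
  s1 <- detect_signals(h$a, ld, K = 1)
  s10 <- detect_signals(h$a, ld, K = 10)
  expect_equal(length(s1), 1L)
  expect_identical(s1[[1]]$lead_key, s10[[1]]$lead_key)
  expect_equal(s1[[1]]$cond_z, s10[[1]]$cond_z)
  # K = 1 lead agrees with an exhaustive single-variant scan (oracle)
  z <- h$a$records$beta / h$a$records$se
  expect_identical(s1[[1]]$lead, which.max(abs(z)))
})

test_that("two weakly linked causal variants are both recovered", {
  # r^2 < 0.01 via separate blocks; marginal |z| ~ 10 (h2 = 0.05, n = 2000)
  hits <- 0L
  reps <- 25L
  for (i in seq_len(reps)) {
    sc <- locus_scenario("DISTINCT", n_a = 2000, n_b = 2000,
                         seed = 5000 + i)
    loc <- simulate_locus(sc)
    # plant BOTH causal variants in a single trait: draw a fresh cohort on
    # the same locus blueprint and give the phenotype both signals
    panel <- loc$panel
    idx <- c(loc$truth$causal_a_idx, loc$truth$causal_b_idx)
    r2 <- cor(panel$dosages[, idx[1]], panel$dosages[, idx[2]])^2
    if (r2 >= 0.01) next
    n <- 2000
    dos <- pqtlx:::draw_dosages(n, loc$blueprint$maf, loc$blueprint$blocks,
                                sc$rho, 99000 + i)
    xs <- scale(dos[, idx])
    set.seed(77000 + i)
    y <- sqrt(0.05) * xs[, 1] + sqrt(0.05) * xs[, 2] + rnorm(n, sd = sqrt(0.9))
    ols <- pqtlx:::marginal_ols(dos, y)
    s <- make_stats(pos = loc$blueprint$pos, beta = ols$beta, se = ols$se,
                    n = n, a1 = loc$blueprint$a1, a2 = loc$blueprint$a2,
                    chrom = "1")
    s$records$eaf <- ols$eaf
    ld <- compute_ld(panel, keys = s$records[c("chrom", "pos", "a1", "a2")])
    sigs <- detect_signals(s, ld)
    if (length(sigs) != 2L) next
    leads <- vapply(sigs, `[[`, 0L, "lead")
    tag <- vapply(seq_along(idx), function(k) {
      max(cor(panel$dosages[, leads], panel$dosages[, idx[k]])^2)
    }, 0)
    if (all(tag > 0.8)) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)   # deeper calibration in the acceptance suite
})

test_that("coloc_pair posteriors normalize and behave at edge cases", {
  # single-variant locus: PP3 is exactly zero
  sa <- make_stats(pos = 1, beta = 0.5, se = 0.05, n = 1000)
  sb <- make_stats(pos = 1, beta = 0.4, se = 0.05, n = 1000)
  ld1 <- identity_ld(sa)
  sig_a <- detect_signals(sa, ld1)[[1]]
  sig_b <- detect_signals(sb, ld1)[[1]]
  cp <- coloc_pair(sig_a, sig_b)
  expect_identical(unname(cp$pp[["PP3"]]), 0)
  expect_equal(sum(cp$pp), 1, tolerance = 1e-9)
  expect_equal(sum(cp$pip), 1, tolerance = 1e-9)
  expect_true(cp$concordant)

  # identical strong statistics for both traits favour the shared hypothesis
  set.seed(41)
  beta <- c(rnorm(9, 0, 0.01), 0.4)
  s2 <- make_stats(pos = 1:10, beta = beta, se = 0.05, n = 1000)
  ld2 <- identity_ld(s2)
  sig <- detect_signals(s2, ld2)[[1]]
  cp2 <- coloc_pair(sig, sig)
  expect_gt(cp2$pp[["PP4"]], cp2$pp[["PP3"]])
  expect_identical(cp2$lead, 10L)
  expect_true(all(cumsum(sort(cp2$pip, decreasing = TRUE))[
    seq_len(length(cp2$credible_set) - 1)] < 0.95))
})

test_that("posterior vectors normalize under randomized inputs", {
  set.seed(55)
  for (i in 1:20) {
    m <- sample(2:30, 1)
    sa <- make_stats(pos = seq_len(m), beta = rnorm(m, 0, 0.1),
                     se = runif(m, 0.01, 0.1), n = 5000)
    sb <- make_stats(pos = seq_len(m), beta = rnorm(m, 0, 0.1),
                     se = runif(m, 0.01, 0.1), n = 5000)
    ld <- identity_ld(sa)
    sig_a <- structure(list(trait = "a", step = 1L, lead = 1L,
                            lead_key = "k", cond_beta = sa$records$beta,
                            cond_se = sa$records$se,
                            cond_z = sa$records$beta / sa$records$se,
                            marg_beta = sa$records$beta,
                            marg_se = sa$records$se,
                            pos = sa$records$pos,
                            keys = paste0("v", seq_len(m)), n = rep(5000, m)),
                       class = "pqtl_signal")
    sig_b <- sig_a
    sig_b$cond_beta <- sb$records$beta
    sig_b$cond_se <- sb$records$se
    sig_b$marg_beta <- sb$records$beta
    cp <- coloc_pair(sig_a, sig_b)
    expect_equal(sum(cp$pp), 1, tolerance = 1e-9)
    expect_equal(sum(cp$pip), 1, tolerance = 1e-9)
    expect_true(length(cp$credible_set) >= 1)
  }
})

test_that("increasing the shared prior p12 never decreases PP4", {
  set.seed(60)
  m <- 15
  sa <- make_stats(pos = 1:m, beta = c(rnorm(m - 1, 0, 0.02), 0.3), se = 0.03,
                   n = 5000)
  sb <- make_stats(pos = 1:m, beta = c(rnorm(m - 1, 0, 0.02), 0.25), se = 0.03,
                   n = 5000)
  ld <- identity_ld(sa)
  sig_a <- detect_signals(sa, ld)[[1]]
  sig_b <- detect_signals(sb, ld)[[1]]
  p12s <- c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3)
  pp4 <- vapply(p12s, function(p12) {
    coloc_pair(sig_a, sig_b, priors = c(1e-4, 1e-4, p12))$pp[["PP4"]]
  }, 0)
  expect_true(all(diff(pp4) >= 0))
})

test_that("trait labels are symmetric: swap maps PP1 to PP2, PP4 unchanged", {
  sc <- locus_scenario("DISTINCT", seed = 71)
  loc <- simulate_locus(sc)
  h <- harmonize_pair(apply_qc(filter_cis(loc$a)), apply_qc(filter_cis(loc$b)))
  ld <- compute_ld(loc$panel, keys = h$a$records[c("chrom", "pos", "a1", "a2")])
  fwd <- colocalize_locus(h$a, h$b, ld)
  rev <- colocalize_locus(h$b, h$a, ld)
  expect_equal(rev$coloc_prob, fwd$coloc_prob, tolerance = 1e-9)
  if (length(fwd$pairs) && length(rev$pairs)) {
    expect_equal(rev$best_pair$pp[["PP1"]], fwd$best_pair$pp[["PP2"]],
                 tolerance = 1e-9)
    expect_equal(rev$best_pair$pp[["PP2"]], fwd$best_pair$pp[["PP1"]],
                 tolerance = 1e-9)
  }
})

test_that("negating one trait's betas flips discordance and nothing else", {
  for (seed in c(81, 82)) {
    loc <- simulate_locus(locus_scenario("SHARED_CONCORDANT", seed = seed))
    cc <- coloc_one(loc)
    if (is.null(cc) || !cc$result$colocalized) next
    b_neg <- cc$h$b
    b_neg$records$beta <- -b_neg$records$beta
    neg <- colocalize_locus(cc$h$a, b_neg, cc$ld)
    expect_equal(neg$coloc_prob, cc$result$coloc_prob, tolerance = 1e-9)
    expect_identical(neg$discordant, !cc$result$discordant)
    expect_identical(neg$best_pair$lead_key, cc$result$best_pair$lead_key)
  }
})

test_that("K = 1 colocalization equals brute-force single-causal enumeration", {
  for (seed in c(91, 92, 93)) {
    loc <- simulate_locus(locus_scenario("SHARED_CONCORDANT", m_variants = 50,
                                         seed = seed))
    cc <- coloc_one(loc, K = 1)
    if (is.null(cc)) next
    ra <- cc$h$a$records
    rb <- cc$h$b$records
    pp_oracle <- oracle_single_coloc(ra$beta, ra$se, ra$n,
                                     rb$beta, rb$se, rb$n)
    expect_lt(max(abs(cc$result$best_pair$pp - pp_oracle)), 1e-9)
  }
})

test_that("cohort concordance summary matches hand-computed rank statistics", {
  mk_res <- function(ba, bb, colocalized = TRUE, discordant = FALSE) {
    structure(list(protein_id = "P", n_signals_a = 1L, n_signals_b = 1L,
                   pairs = list(), coloc_prob = if (colocalized) 0.95 else 0.1,
                   colocalized = colocalized,
                   discordant = if (colocalized) discordant else NA,
                   best_pair = list(lead_beta_a = ba, lead_beta_b = bb)),
              class = "locus_coloc_result")
  }
  # hand-computed Spearman rho for (1,2),(2,1),(3,4),(4,3),(5,5):
  # d^2 = (1,1,1,1,0), rho = 1 - 6*4/(5*24) = 0.8
  res <- list(mk_res(1, 2), mk_res(2, 1), mk_res(3, 4), mk_res(4, 3),
              mk_res(5, 5), mk_res(9, 9, colocalized = FALSE))
  s <- summarize_concordance(res)
  expect_equal(s$n_tested, 6L)
  expect_equal(s$n_colocalized, 5L)
  expect_equal(s$spearman_rho, 0.8)
  # perfect agreement and perfect reversal
  res_eq <- list(mk_res(1, 1), mk_res(2, 2), mk_res(3, 3))
  expect_equal(summarize_concordance(res_eq)$spearman_rho, 1)
  res_rev <- list(mk_res(1, -1), mk_res(2, -2), mk_res(3, -3))
  expect_equal(summarize_concordance(res_rev)$spearman_rho, -1)
  # fewer than 2 colocalized: rho absent
  expect_true(is.na(summarize_concordance(list(mk_res(1, 1)))$spearman_rho))
  # discordance bookkeeping
  resd <- list(mk_res(1, 1), mk_res(2, -2, discordant = TRUE))
  expect_equal(summarize_concordance(resd)$prop_discordant_among_colocalized, 0.5)
})
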