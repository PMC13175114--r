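# Multi-signal colocalization from summary statistics:
#   1. stepwise approximate conditional analysis (COJO-style, standardized
#      scale b = z / sqrt(n)) detects up to K independent signals per trait;
#   2. each cross-trait signal pair is colocalized with Wakefield approximate
#      Bayes factors under the five-hypothesis enumeration (H0..H4);
#   3. the locus-level colocalization probability is the maximum shared-
#      variant posterior (PP4) across greedily matched signal pairs.

# Two-sided p = 5e-8 on the |z| scale.
Z_GWAS <- 5.4513

#' Conditional summary statistics given a selected variant set
#'
#' Standardized-scale approximate conditional analysis: for variant j and
#' selected index set S,
#' `b_{j|S} = b_j - R_jS (R_SS + eps I)^{-1} b_S` with
#' `se_{j|S} = sqrt((1 - q_j) / n_j)` where
#' `q_j = R_jS (R_SS + eps I)^{-1} R_Sj`. Variants whose `q_j` exceeds the
#' collinearity guard (including members of S itself) are returned as null
#' (`beta = 0`, `se = 1/sqrt(n)`) since their conditional effect is not
#' identifiable from the reference LD.
#'
#' @param b Standardized marginal effects `z / sqrt(n)`.
#' @param n Per-variant sample sizes.
#' @param R LD correlation matrix.
#' @param S Integer indices of the conditioning set (may be empty).
#' @param ridge Ridge constant added to `R_SS` (default 1e-6).
#' @param collinearity_max Guard on `q_j` (default 0.95).
#' @return List with `beta`, `se`, `z`, `q` vectors.
#' @keywords internal
conditional_stats <- function(b, n, R, S, ridge = 1e-6,
                              collinearity_max = 0.95) {
  m <- length(b)
  if (length(S) == 0L) {
    se <- 1 / sqrt(n)
    return(list(beta = b, se = se, z = b / se, q = rep(0, m)))
  }
  A <- R[S, S, drop = FALSE] + diag(ridge, length(S))
  RjS <- R[, S, drop = FALSE]
  W <- tryCatch(RjS %*% solve(A),
                error = function(e) stop("singular conditioning matrix despite ridge: ",
                                         conditionMessage(e), call. = FALSE))
  q <- rowSums(W * RjS)
  beta <- as.vector(b - W %*% b[S])
  guard <- q > collinearity_max
  q <- pmin(pmax(q, 0), 1)
  se <- sqrt(pmax(1 - q, 1e-12) / n)
  beta[guard] <- 0
  se[guard] <- 1 / sqrt(n[guard])
  list(beta = beta, se = se, z = beta / se, q = q)
}

#' Detect independent cis association signals by stepwise conditional analysis
#'
#' Forward selection on the standardized scale `b = z/sqrt(n)`: at each step
#' the variant with the largest conditional |z| among candidates passing the
#' collinearity guard is added, until no conditional |z| reaches `z_thresh`
#' (|z| for two-sided p = 5e-8 by default) or `K` signals are selected. Ties
#' in |z| break to the smaller position. Each returned signal carries
#' leave-one-out conditional effect/SE arrays over the whole locus (its own
#' lead left out of the conditioning set), which downstream colocalization
#' consumes.
#'
#' @param stats A harmonized `locus_sumstats`, orientation-consistent with
#'   `ld`.
#' @param ld An `ld_matrix` over the same variants in the same order.
#' @param z_thresh Selection threshold on conditional |z| (default 5.4513).
#' @param K Maximum number of signals (default 10).
#' @param ridge Ridge constant for the conditioning solve.
#' @param collinearity_max Collinearity guard on `q` (default 0.95).
#' @param trait Label stored on the returned signals.
#' @return List of `pqtl_signal` objects (possibly empty), each with fields
#'   `trait`, `step`, `lead` (index), `lead_key`, `cond_beta`, `cond_se`,
#'   `cond_z`, `marg_beta`, `marg_se`.
#' @export
detect_signals <- function(stats, ld, z_thresh = Z_GWAS, K = 10,
                           ridge = 1e-6, collinearity_max = 0.95,
                           trait = NA_character_) {
  stopifnot(inherits(stats, "locus_sumstats"), inherits(ld, "ld_matrix"))
  rec <- stats$records
  m <- nrow(rec)
  if (m == 0L) return(list())
  if (m != nrow(ld$r)) stop("summary statistics and LD matrix differ in size")
  kstats <- variant_match_key(rec$chrom, rec$pos, rec$a1, rec$a2)
  kld <- variant_match_key(ld$variants$chrom, ld$variants$pos,
                           ld$variants$a1, ld$variants$a2)
  if (!identical(kstats, kld)) stop("summary statistics and LD matrix are not index-aligned")
  if (any(rec$a1 != ld$variants$a1)) {
    stop("LD matrix orientation differs from harmonized effect alleles")
  }
  n <- rec$n
  if (anyNA(n) || any(!is.finite(n))) {
    med <- stats::median(n[is.finite(n)])
    if (!is.finite(med)) stop("sample size missing for entire locus")
    warning("missing per-variant n; using locus median", call. = FALSE)
    n[!is.finite(n)] <- med
  }
  z <- rec$beta / rec$se
  b <- z / sqrt(n)
  R <- ld$r

  S <- integer(0)
  repeat {
    cond <- conditional_stats(b, n, R, S, ridge, collinearity_max)
    cand <- setdiff(which(cond$q <= collinearity_max), S)
    if (length(cand) == 0L) break
    az <- abs(cond$z[cand])
    best <- cand[order(-az, rec$pos[cand])][1]
    if (abs(cond$z[best]) < z_thresh) break
    S <- c(S, best)
    if (length(S) >= K) break
  }
  lapply(seq_along(S), function(i) {
    loo <- conditional_stats(b, n, R, S[-i], ridge, collinearity_max)
    structure(list(trait = trait, step = i, lead = S[i],
                   lead_key = kstats[S[i]],
                   cond_beta = loo$beta, cond_se = loo$se, cond_z = loo$z,
                   marg_beta = rec$beta, marg_se = rec$se,
                   pos = rec$pos, keys = kstats, n = n),
              class = "pqtl_signal")
  })
}

#' Wakefield approximate log Bayes factor
#'
#' For an estimate `beta` with variance `V = se^2` and a Gaussian effect
#' prior with variance `W`:
#' `log ABF = 0.5 log(V / (V + W)) + (z^2 / 2) (W / (V + W))`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior effect variance (default 0.0225 = 0.15^2 on the
#'   standardized scale).
#' @return Log Bayes factor(s), vectorized.
#' @export
wakefield_log_abf <- function(beta, se, W = 0.0225) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W)) {
    stop("non-finite input to wakefield_log_abf")
  }
  if (any(se <= 0)) stop("se must be positive")
  if (W < 0) stop("prior variance W must be non-negative")
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + (z2 / 2) * (W / (V + W))
}

#' Colocalize one cross-trait signal pair
#'
#' Per-variant log ABFs are computed from each signal's leave-one-out
#' conditional statistics. The five hypotheses are enumerated in log space:
#' `L1 = sum_k A_k`, `L2 = sum_k B_k`, `L12 = sum_k A_k B_k`,
#' `Lcross = L1 L2 - L12` (the sum over distinct variant pairs), with
#' unnormalized weights `{1, p1 L1, p2 L2, p1 p2 Lcross, p12 L12}` giving
#' PP0..PP4. Per-variant posterior inclusion probabilities under the shared
#' hypothesis are `A_k B_k / sum(A B)`; the credible set is the smallest
#' PIP-descending prefix reaching `cs_mass`. Direction concordance compares
#' the signs of the two traits' marginal betas at the lead (max-PIP) variant.
#'
#' @param sig_a,sig_b `pqtl_signal` objects with index-aligned arrays.
#' @param priors Numeric vector `(p1, p2, p12)` of per-variant prior
#'   probabilities (default `c(1e-4, 1e-4, 1e-5)`).
#' @param W Wakefield prior variance (default 0.0225).
#' @param cs_mass Credible-set mass (default 0.95).
#' @return Object of class `coloc_pair`: `pp` (named PP0..PP4 vector),
#'   `pip`, `credible_set` (variant keys), `lead_key`, `lead` (index),
#'   `lead_pip`, `concordant`, `lead_beta_a`, `lead_beta_b`, `step_a`,
#'   `step_b`.
#' @export
coloc_pair <- function(sig_a, sig_b, priors = c(1e-4, 1e-4, 1e-5),
                       W = 0.0225, cs_mass = 0.95) {
  stopifnot(inherits(sig_a, "pqtl_signal"), inherits(sig_b, "pqtl_signal"))
  m <- length(sig_a$cond_beta)
  if (length(sig_b$cond_beta) != m) stop("signal arrays are not index-aligned")
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  A <- wakefield_log_abf(sig_a$cond_beta, sig_a$cond_se, W)
  B <- wakefield_log_abf(sig_b$cond_beta, sig_b$cond_se, W)
  l1 <- logsumexp(A)
  l2 <- logsumexp(B)
  l12 <- logsumexp(A + B)
  # Lcross = L1*L2 - L12 >= 0 (sum over j != k); stabilized in logs. A
  # single-variant locus forces Lcross = 0 and hence PP3 = 0 exactly.
  lcross <- if (m == 1L) -Inf else {
    d <- l12 - (l1 + l2)
    if (d >= 0) -Inf else l1 + l2 + log1p(-exp(d))
  }
  lw <- c(0,
          log(p1) + l1,
          log(p2) + l2,
          log(p1) + log(p2) + lcross,
          log(p12) + l12)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("PP", 0:4)
  lab <- A + B
  pip <- exp(lab - logsumexp(lab))
  ord <- order(-pip, sig_a$pos)
  n_cs <- which(cumsum(pip[ord]) >= cs_mass)[1]
  if (is.na(n_cs)) n_cs <- m
  cs_idx <- ord[seq_len(n_cs)]
  lead <- ord[1]
  ba <- sig_a$marg_beta[lead]
  bb <- sig_b$marg_beta[lead]
  structure(list(pp = pp, pip = pip,
                 credible_set = sig_a$keys[cs_idx],
                 lead = lead, lead_key = sig_a$keys[lead],
                 lead_pip = pip[lead],
                 lead_beta_a = ba, lead_beta_b = bb,
                 concordant = sign(ba) == sign(bb),
                 step_a = sig_a$step, step_b = sig_b$step),
            class = "coloc_pair")
}

#' @export
print.coloc_pair <- function(x, ...) {
  cat(sprintf("coloc_pair: PP4 = %.3f, lead %s (pip %.3f), %s\n",
              x$pp["PP4"], x$lead_key, x$lead_pip,
              if (isTRUE(x$concordant)) "concordant" else "discordant"))
  invisible(x)
}

#' Colocalize a harmonized locus across two traits
#'
#' Detects up to `K` conditional signals per trait, evaluates every
#' cross-trait signal pair, and greedily matches pairs by descending PP4 with
#' each signal used at most once. The locus colocalization probability is the
#' maximum PP4 over matched pairs; the locus is called colocalized when it
#' strictly exceeds `coloc_threshold`. Discordance (defined only for
#' colocalized loci) comes from the best pair's lead-variant sign comparison.
#'
#' @param a,b Harmonized `locus_sumstats` (index-aligned).
#' @param ld `ld_matrix` aligned to the harmonized variants.
#' @param K Maximum signals per trait (default 10).
#' @param z_thresh Signal-selection threshold (default 5.4513).
#' @param priors,W,cs_mass Passed to [coloc_pair()].
#' @param coloc_threshold Call threshold on PP4 (default 0.8, strict).
#' @return Object of class `locus_coloc_result`: `protein_id`,
#'   `n_signals_a`, `n_signals_b`, `pairs` (matched `coloc_pair`s, PP4
#'   descending), `best_pair`, `coloc_prob`, `colocalized`, `discordant`
#'   (`NA` unless colocalized).
#' @export
colocalize_locus <- function(a, b, ld, K = 10, z_thresh = Z_GWAS,
                             priors = c(1e-4, 1e-4, 1e-5), W = 0.0225,
                             cs_mass = 0.95, coloc_threshold = 0.8) {
  sigs_a <- detect_signals(a, ld, z_thresh = z_thresh, K = K, trait = "a")
  sigs_b <- detect_signals(b, ld, z_thresh = z_thresh, K = K, trait = "b")
  pairs <- list()
  if (length(sigs_a) && length(sigs_b)) {
    all_pairs <- vector("list", length(sigs_a) * length(sigs_b))
    pp4 <- matrix(NA_real_, length(sigs_a), length(sigs_b))
    for (i in seq_along(sigs_a)) {
      for (j in seq_along(sigs_b)) {
        cp <- coloc_pair(sigs_a[[i]], sigs_b[[j]], priors = priors, W = W,
                         cs_mass = cs_mass)
        all_pairs[[(i - 1) * length(sigs_b) + j]] <- cp
        pp4[i, j] <- cp$pp["PP4"]
      }
    }
    # greedy one-to-one matching by descending PP4
    avail <- pp4
    repeat {
      if (all(is.na(avail))) break
      ij <- which(avail == max(avail, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <-
        all_pairs[[(ij[1] - 1) * length(sigs_b) + ij[2]]]
      avail[ij[1], ] <- NA
      avail[, ij[2]] <- NA
    }
  }
  best <- if (length(pairs)) pairs[[1]] else NULL
  coloc_prob <- if (length(pairs)) max(vapply(pairs, function(p) p$pp[["PP4"]],
                                              0)) else 0
  colocalized <- coloc_prob > coloc_threshold
  structure(list(protein_id = a$protein_id,
                 n_signals_a = length(sigs_a), n_signals_b = length(sigs_b),
                 pairs = pairs, best_pair = best,
                 coloc_prob = coloc_prob, colocalized = colocalized,
                 discordant = if (colocalized) !best$concordant else NA),
            class = "locus_coloc_result")
}

#' @export
print.locus_coloc_result <- function(x, ...) {
  cat(sprintf("locus_coloc_result: %s, signals %d/%d, coloc_prob %.3f (%s)\n",
              x$protein_id, x$n_signals_a, x$n_signals_b, x$coloc_prob,
              if (x$colocalized) {
                if (isTRUE(x$discordant)) "colocalized, discordant"
                else "colocalized, concordant"
              } else "not colocalized"))
  invisible(x)
}

#' Cohort-level concordance summary across loci
#'
#' Reports how many loci were tested and colocalized, the discordant
#' fraction among colocalized loci, and Spearman's rank correlation of the
#' two traits' marginal lead-variant effect estimates across colocalized
#' loci (the rho is `NA` with fewer than 2 colocalized loci).
#'
#' @param results List of `locus_coloc_result`.
#' @return List with `n_tested`, `n_colocalized`, `prop_colocalized`,
#'   `n_discordant`, `prop_discordant_among_colocalized`, `spearman_rho`.
#' @export
summarize_concordance <- function(results) {
  stopifnot(all(vapply(results, inherits, TRUE, "locus_coloc_result")))
  n_tested <- length(results)
  coloc <- Filter(function(r) isTRUE(r$colocalized), results)
  n_coloc <- length(coloc)
  n_disc <- sum(vapply(coloc, function(r) isTRUE(r$discordant), TRUE))
  beta_a <- vapply(coloc, function(r) r$best_pair$lead_beta_a, 0)
  beta_b <- vapply(coloc, function(r) r$best_pair$lead_beta_b, 0)
  rho <- if (n_coloc >= 2) stats::cor(beta_a, beta_b, method = "spearman")
         else NA_real_
  list(n_tested = n_tested,
       n_colocalized = n_coloc,
       prop_colocalized = if (n_tested) n_coloc / n_tested else NA_real_,
       n_discordant = n_disc,
       prop_discordant_among_colocalized =
         if (n_coloc) n_disc / n_coloc else NA_real_,
       spearman_rho = rho)
}
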